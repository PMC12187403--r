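test_that("the packaged genotype table reads with order and calls intact", {
  gm <- tbl1_gm()
  expect_s3_class(gm, "genotype_matrix")
  expect_length(gm$cultivars, 12L)
  expect_length(gm$loci, 18L)
  expect_identical(gm$cultivars[1L], "741")
  expect_identical(gm$cultivars[12L], "Own Venture")
  expect_identical(genotype(gm, "741", "27718"), "TT")
  expect_identical(genotype(gm, "A29", "27718"), "GT")
  expect_true(is.na(genotype(gm, "842", "13501")))
  # genotypes are unordered pairs: "TG" and "GT" are the same call
  expect_identical(genotype(gm, "A38", "27718"), "GT")
})

test_that("reader rejects malformed cells and duplicate loci by name", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("locus,a,b", "L1,GTT,GG"), tf)
  expect_error(read_genotype_table(tf), "GTT.*L1.*a|L1.*a.*GTT")
  writeLines(c("locus,a,b", "L1,GG,GG", "L1,TT,GG"), tf)
  expect_error(read_genotype_table(tf), "duplicate locus")
  writeLines(c("locus,a,b", "L1,NA,NA"), tf)
  gm <- read_genotype_table(tf)
  expect_true(all(is.na(gm$geno)))
})

test_that("private-allele discovery reproduces the published panel", {
  pd <- find_private_alleles(tbl1_gm())
  expect_length(pd$loci, 18L)
  expect_identical(nrow(pd$excluded), 0L)
  l1 <- pd$loci[["27718"]]
  expect_identical(l1$target, "741")
  expect_identical(l1$ref, "G")
  expect_identical(l1$alt, "T")
  expect_setequal(l1$het_carriers, c("A29", "A38"))
  expect_identical(pd$loci[["13501"]]$target, "849")
  expect_identical(pd$loci[["13501"]]$missing, "842")
  expect_identical(pd$loci[["74523"]]$missing, "816")
  # the published table shows two homozygous carriers of the ALT base at
  # locus 8730; the locus is kept but flagged non-unique
  expect_false(pd$loci[["8730"]]$unique)
  expect_setequal(pd$loci[["8730"]]$hom_alt, c("A4", "A16"))
  expect_identical(pd$loci[["8730"]]$target, "A4")
  # the as-printed CT calls at 52998 carry an allele outside {REF, ALT}
  expect_setequal(pd$loci[["52998"]]$anomalies, c("A29", "A38"))
  expect_length(pd$loci[["52998"]]$het_carriers, 0L)
})

test_that("uninformative and reciprocal loci are excluded with reasons", {
  geno <- rbind(
    mono = c(a = "GG", b = "GG", c = "GG"),
    recip = c(a = "AA", b = "CC", c = "AC"),
    good = c(a = "TT", b = "GG", c = "GG"))
  pd <- find_private_alleles(genotype_matrix(geno))
  expect_identical(names(pd$loci), "good")
  expect_setequal(pd$excluded$locus, c("mono", "recip"))
})

test_that("discovery is invariant to row and column permutation", {
  gm <- tbl1_gm()
  set.seed(1)
  gm2 <- genotype_matrix(gm$geno[sample(nrow(gm$geno)),
                                 sample(ncol(gm$geno))])
  pd1 <- find_private_alleles(gm)
  pd2 <- find_private_alleles(gm2)
  expect_setequal(names(pd1$loci), names(pd2$loci))
  for (lid in names(pd1$loci)) {
    expect_identical(pd1$loci[[lid]]$alt, pd2$loci[[lid]]$alt)
    expect_setequal(pd1$loci[[lid]]$hom_alt, pd2$loci[[lid]]$hom_alt)
    expect_setequal(pd1$loci[[lid]]$het_carriers,
                    pd2$loci[[lid]]$het_carriers)
  }
})

test_that("discovery matches the exhaustive (locus, base, cultivar) scan", {
  for (seed in 1:8) {
    gm <- random_gm(n_cultivar = sample(3:8, 1), n_loci = 40, seed = seed)
    pd <- find_private_alleles(gm)
    orc <- oracle_private_alleles(gm$geno)
    expect_setequal(names(pd$loci), names(orc))
    for (lid in names(orc)) {
      expect_identical(pd$loci[[lid]]$alt, orc[[lid]]$alt, info = lid)
      expect_identical(pd$loci[[lid]]$target, orc[[lid]]$target,
                       info = lid)
      expect_setequal(pd$loci[[lid]]$het_carriers,
                      orc[[lid]]$het_carriers)
    }
  }
})

test_that("multiplex groups partition the panel by extension base", {
  pd <- tbl1_pd()
  expect_setequal(pd$multiplex_groups_alt[["T"]],
                  c("27718", "3756", "13501", "74523", "8730", "3801",
                    "60567", "86621"))
  all_alt <- unlist(pd$multiplex_groups_alt)
  all_ref <- unlist(pd$multiplex_groups_ref)
  expect_setequal(all_alt, names(pd$loci))
  expect_setequal(all_ref, names(pd$loci))
  expect_identical(anyDuplicated(all_alt), 0L)
  expect_identical(anyDuplicated(all_ref), 0L)
  # single locus: one group of size one under its ALT base
  geno <- rbind(solo = c(a = "TT", b = "GG", c = "GG"))
  pd1 <- find_private_alleles(genotype_matrix(geno))
  expect_identical(pd1$multiplex_groups_alt, list(T = "solo"))
})

test_that("panel validation passes the full published panel", {
  gm <- tbl1_gm()
  rep <- validate_panel(find_private_alleles(gm), gm)
  expect_true(rep$pass)
  expect_true(all(rep$cultivars$n_diagnostic >= 1L))
  multi <- rep$cultivars$cultivar[rep$cultivars$n_diagnostic >= 2L]
  expect_true(all(c("741", "849", "A38", "Own Venture") %in% multi))
  expect_setequal(unique(rep$warnings$locus),
                  c("27718", "52998", "10725", "24338", "8730", "1724"))
  expect_setequal(rep$flagged_na, c("13501", "74523"))
})

test_that("validation adapts when a cultivar is removed or duplicated", {
  gm <- tbl1_gm()
  # dropping A29 leaves 11 identifiable cultivars and kills locus 3801
  gm11 <- genotype_matrix(gm$geno[, gm$cultivars != "A29"])
  pd11 <- find_private_alleles(gm11)
  rep11 <- validate_panel(pd11, gm11)
  expect_true(rep11$pass)
  expect_identical(nrow(rep11$cultivars), 11L)
  expect_false("3801" %in% names(pd11$loci))
  expect_true("3801" %in% pd11$excluded$locus)
  # a duplicated cultivar column cannot be told apart from its twin
  geno <- gm$geno
  geno <- cbind(geno, `816-copy` = geno[, "816"])
  gm13 <- genotype_matrix(geno)
  rep13 <- validate_panel(find_private_alleles(gm13), gm13)
  expect_false(rep13$pass)
  bad <- rep13$cultivars[rep13$cultivars$cultivar %in%
                           c("816", "816-copy"), ]
  expect_true(all(bad$n_diagnostic == 0L))
})

test_that("panel export writes the documented columns", {
  pd <- tbl1_pd()
  tf <- tempfile(fileext = ".csv")
  export_panel(pd, tf, header_lines = "test")
  df <- utils::read.csv(tf, comment.char = "#",
                        colClasses = c(locus_id = "character"))
  expect_identical(names(df), c("locus_id", "ref", "alt", "target",
                                "het_carriers", "missing", "alt_group",
                                "ref_group"))
  expect_identical(nrow(df), 18L)
  expect_identical(df$target[df$locus_id == "10725"], "816")
})
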
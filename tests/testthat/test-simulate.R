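test_that("orchard presets lay out the documented blocks and spacings", {
  wide <- build_orchard(orchard_preset("wide")$orchard, seed = 1L)
  expect_identical(wide$blocks$cultivar, c("816", "Daddow"))
  expect_identical(wide$blocks$n_rows, c(42L, 48L))
  expect_identical(wide$row_spacing_m, 8)
  expect_identical(wide$tree_spacing_m, 4)
  narrow <- build_orchard(orchard_preset("narrow")$orchard, seed = 1L)
  expect_identical(narrow$blocks$cultivar,
                   c("A203", "842", "816", "A4", "741"))
  expect_true(all(narrow$blocks$n_rows == 5L))
  expect_identical(narrow$row_spacing_m, 10)
  expect_identical(narrow$tree_spacing_m, 2)
  # no off-types: every tree matches its block cultivar
  expect_identical(narrow$grid, narrow$planted)
  expect_error(build_orchard(list(blocks = list(
    list(cultivar = "X9", n_rows = 2))), cultivars = c("816", "741")),
    "unknown cultivar")
  expect_error(build_orchard(list(blocks = list(
    list(cultivar = "816", n_rows = 0)))), "n_rows")
})

test_that("foraging trips respect their parameters and seeds", {
  lay <- build_orchard(orchard_preset("wide")$orchard, seed = 1L)
  fp0 <- list(p_row_switch = 0, n_visits = 20L, carryover_retention = 0.7,
              pickup_grains = 1, capture_visit = 20L)
  # no row switching, start inside the 816 block: only 816 pollen
  tr <- simulate_trip(lay, fp0, start = c(20L, 25L), seed = 3L)
  expect_identical(names(tr$grains), "816")
  # zero carryover: only the last visited tree's cultivar remains
  fpr0 <- utils::modifyList(fp0, list(carryover_retention = 0,
                                      p_row_switch = 0.3))
  tr2 <- simulate_trip(lay, fpr0, start = c(42L, 25L), seed = 9L)
  last <- tr2$visits[nrow(tr2$visits), ]
  expect_identical(names(tr2$grains), last$cultivar)
  # exact bookkeeping: total load is a geometric sum of pickups
  rho <- 0.7; u <- 20L
  expect_equal(sum(tr$grains), sum(rho^(seq_len(u) - 1L)))
  # reproducibility
  expect_identical(simulate_trip(lay, fpr0, c(10L, 10L), seed = 11L),
                   simulate_trip(lay, fpr0, c(10L, 10L), seed = 11L))
  expect_error(simulate_trip(lay, utils::modifyList(
    fp0, list(capture_visit = 21L)), c(1L, 1L)), "capture_visit")
  expect_error(simulate_trip(lay, fp0, c(999L, 1L)), "outside layout")
})

test_that("assay dosage model fires the documented loci", {
  pd <- tbl1_pd()
  ap <- list(theta_detect = 0.01, fn_rate = 0, fp_rate = 0)
  # pure 741 pollen: exactly the two 741 signature loci fire
  cl <- simulate_assay(list(grains = c(`741` = 10)), pd, ap)
  expect_setequal(cl$locus_id[cl$alt_detected], c("27718", "52998"))
  # REF assay fires everywhere 741 carries the predominant allele
  expect_false(cl$ref_detected[cl$locus_id == "27718"])
  expect_true(cl$ref_detected[cl$locus_id == "3756"])
  # 5% admixture: detected at theta 0.01 but not at theta 0.10
  mix <- list(grains = c(`816` = 95, `741` = 5))
  hi <- simulate_assay(mix, pd, list(theta_detect = 0.10))
  lo <- simulate_assay(mix, pd, list(theta_detect = 0.01))
  expect_false(any(hi$alt_detected[hi$locus_id %in% c("27718", "52998")]))
  expect_true(all(lo$alt_detected[lo$locus_id %in% c("27718", "52998")]))
  # het carriage sheds half dosage: 50% A29 fires 27718 at theta 0.25
  a29 <- list(grains = c(`816` = 50, `A29` = 50))
  cl3 <- simulate_assay(a29, pd, list(theta_detect = 0.25))
  expect_true(cl3$alt_detected[cl3$locus_id == "27718"])
  expect_true(cl3$alt_detected[cl3$locus_id == "3801"])
  # certain false negatives kill every detection
  none <- simulate_assay(list(grains = c(`741` = 1)), pd,
                         list(theta_detect = 0.01, fn_rate = 1,
                              seed = 1L))
  expect_false(any(none$alt_detected))
  # empty load: all-false calls, not an error
  empty <- simulate_assay(list(grains = numeric(0)), pd, ap)
  expect_false(any(empty$alt_detected))
  expect_error(simulate_assay(list(grains = c(X1 = 1)), pd, ap),
               "not in panel")
})

test_that("study generation follows the configured design exactly", {
  wide <- orchard_preset("wide")
  st <- generate_study(wide, seed = 2L)
  expect_identical(nrow(st$metadata), 8L * 4L * 6L)   # 192 bees
  expect_setequal(unique(st$metadata$row_index), c(1L, 2L, 3L, 11L))
  expect_identical(unique(st$metadata$orchard_type), "WIDE")
  expect_setequal(unique(st$metadata$distance_m), c(8, 16, 24, 88))
  expect_identical(length(unique(st$metadata$transect_id)), 8L)
  narrow <- orchard_preset("narrow")
  stn <- generate_study(narrow, seed = 2L)
  expect_identical(nrow(stn$metadata), 7L * 4L * 6L)  # 168 bees
  expect_setequal(unique(stn$metadata$host_cultivar), c("816", "A4"))
  bad <- narrow
  bad$transects$bees_per_point <- 0L
  expect_error(generate_study(bad, seed = 1L), "bees_per_point")
})

test_that("identical seeds give byte-identical study files", {
  cfg <- small_config("narrow")
  cfg$transects$hosts[[2]] <- NULL
  cfg$transects$hosts[[1]]$n_transects <- 2L
  d1 <- file.path(tempdir(), "study_a"); d2 <- file.path(tempdir(),
                                                         "study_b")
  generate_study(cfg, seed = 7L, outdir = d1)
  generate_study(cfg, seed = 7L, outdir = d2)
  for (f in c("bee_metadata.csv", "allele_calls.csv",
              "ground_truth.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("clean round trip: pipeline categories equal ground truth", {
  # loads whose fractions keep homozygous dosage above and heterozygous
  # dosage below the detection threshold, so every present cultivar's
  # signature -- and nothing else -- fires
  pd <- tbl1_pd()
  fracs <- list(1, c(0.6, 0.4), c(0.4, 0.33, 0.27))
  set.seed(99)
  for (i in 1:40) {
    k <- sample(1:3, 1L)
    M <- sample(pd$cultivars, k)
    load <- stats::setNames(fracs[[k]] * 100, M)
    # threshold between the largest het dosage (max fraction / 2) and the
    # smallest hom dosage (min fraction)
    theta <- (max(fracs[[k]]) / 2 + min(fracs[[k]])) / 2
    ap <- list(theta_detect = theta, fn_rate = 0, fp_rate = 0)
    host <- sample(pd$cultivars, 1L)
    cl <- simulate_assay(list(grains = load), pd, ap)
    fired <- cl$locus_id[cl$alt_detected]
    # the clean-signal premise: every present cultivar's signature fires
    # and nothing else.  Mixtures whose het carriages stack above the
    # threshold at a shared locus (e.g. A29 + 849 at 1724) violate it --
    # a physical aliasing of the assay, not a deconvolution case.
    if (!setequal(fired, signature_calls(pd, M))) next
    pres <- interpret_calls(fired, pd)
    got <- classify_bee(pres, host, pd)$category
    self <- host %in% M
    cross <- length(setdiff(M, host)) > 0L
    want <- if (cross && self) "MIXED" else if (cross) "CROSS_ONLY"
      else "SELF_ONLY"
    expect_identical(got, want, info = paste(M, collapse = "+"))
  }
})

test_that("more off-type trees means weakly more cross-pollen carriage", {
  cfg <- small_config("wide")
  cfg$transects$hosts[[1]]$n_transects <- 3L
  cfg$transects$rows <- c(2L, 3L)
  cfg$assay$fn_rate <- 0; cfg$assay$fp_rate <- 0
  carr <- vapply(c(0, 0.08, 0.25), function(rate) {
    cfg$orchard$offtype_rate <- rate
    cfg$orchard$offtype_pool <- c("741", "849")
    st <- generate_study(cfg, seed = 31L)   # common random numbers
    inc <- st$truth$true_category != "UNDETERMINED"
    mean(st$truth$true_category[inc] != "SELF_ONLY")
  }, numeric(1L))
  expect_true(all(diff(carr) >= 0))
  expect_gt(carr[3L], carr[1L])
})
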
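# shared fixtures and independent oracles

tbl1_path <- function() {
  system.file("extdata", "table1_genotypes.tsv", package = "pollenpanel")
}

tbl1_gm <- function() read_genotype_table(tbl1_path())

tbl1_pd <- function() table1_panel()

# diagnostic (homozygous-ALT) signature of each cultivar, from the dosage
# matrix
hom_signatures <- function(pd) {
  sig <- lapply(pd$cultivars, function(c)
    rownames(pd$dosage)[!is.na(pd$dosage[, c]) & pd$dosage[, c] == 2L])
  names(sig) <- pd$cultivars
  sig
}

# the idealized call pattern of a cultivar mixture: every diagnostic locus
# of every present cultivar fires, nothing else
signature_calls <- function(pd, mixture) {
  sig <- hom_signatures(pd)
  unique(unlist(sig[mixture]))
}

# --- independent brute-force oracle for private-allele discovery ---------
# exhaustive scan over every (locus, base, cultivar) triple, written
# directly from the definition: REF is the base with the most homozygotes
# (unique maximum), ALT the single other base with any homozygote.
oracle_private_alleles <- function(geno) {
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (lid in rownames(geno)) {
    calls <- geno[lid, ]
    hom <- list()
    for (b in bases) {
      who <- character(0)
      for (cv in colnames(geno)) {
        g <- calls[[cv]]
        if (!is.na(g) && g != "NA" &&
            substr(g, 1, 1) == b && substr(g, 2, 2) == b)
          who <- c(who, cv)
      }
      if (length(who)) hom[[b]] <- who
    }
    if (length(hom) == 0) next
    counts <- sapply(hom, length)
    if (sum(counts == max(counts)) > 1) next
    ref <- names(which.max(counts))
    alts <- setdiff(names(hom), ref)
    if (length(alts) != 1) next
    alt <- alts
    het <- character(0)
    for (cv in colnames(geno)) {
      g <- calls[[cv]]
      if (is.na(g) || g == "NA") next
      n_alt <- sum(strsplit(g, "")[[1]] == alt)
      if (n_alt == 1) het <- c(het, cv)
    }
    out[[lid]] <- list(locus_id = lid, ref = ref, alt = alt,
                       hom_alt = hom[[alt]], target = hom[[alt]][1],
                       het_carriers = het,
                       missing = colnames(geno)[is.na(calls) |
                                                  calls == "NA"],
                       unique = length(hom[[alt]]) == 1)
  }
  out
}

# random genotype matrix: mostly hom-REF with occasional hom-ALT, het and
# missing calls
random_gm <- function(n_cultivar, n_loci, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  cvs <- paste0("cv", seq_len(n_cultivar))
  geno <- matrix(NA_character_, n_loci, n_cultivar,
                 dimnames = list(paste0("L", seq_len(n_loci)), cvs))
  for (i in seq_len(n_loci)) {
    rb <- sample(bases, 2)
    g <- sample(c(paste0(rb[1], rb[1]), paste0(rb[2], rb[2]),
                  paste0(sort(rb), collapse = ""), NA),
                n_cultivar, replace = TRUE,
                prob = c(0.7, 0.15, 0.1, 0.05))
    geno[i, ] <- g
  }
  genotype_matrix(geno)
}

# --- independent Newton-Raphson logistic regression oracle ---------------
nr_logistic <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    score <- t(X) %*% (y - mu)
    info <- t(X) %*% (X * W)
    step <- solve(info, score)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  names(beta) <- colnames(X)
  beta
}

# simulate bee-level score data from the binomial mixed model itself
sim_score_data <- function(n_transects, bees_per_row, rows, beta0,
                           beta_distance, sigma, orchard = "WIDE") {
  tr <- rep(seq_len(n_transects), each = bees_per_row * length(rows))
  rowv <- rep(rep(rows, each = bees_per_row), times = n_transects)
  u <- stats::rnorm(n_transects, 0, sigma)[tr]
  p <- stats::plogis(beta0 + beta_distance * rowv + u)
  data.frame(bee_id = paste0("b", seq_along(p)),
             transect_id = paste0("t", tr), row_index = rowv,
             distance_m = rowv * 8, orchard_type = orchard,
             host_cultivar = "816",
             score = stats::rbinom(length(p), 1, p),
             category = "included")
}

# small complete study config for fast pipeline tests
small_config <- function(base = "narrow", ...) {
  cfg <- orchard_preset(base)
  mods <- list(...)
  for (nm in names(mods)) {
    path <- strsplit(nm, "\\.")[[1]]
    cfg[[path]] <- mods[[nm]]
  }
  cfg
}
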
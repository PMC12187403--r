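#' Derive a private-allele diagnostic panel from a genotype matrix
#'
#' Scans every locus of a genotype matrix for a private allele: an
#' alternative base (ALT) for which one cultivar -- the locus's target -- is
#' homozygous while the predominant base (REF) is homozygous in most other
#' cultivars.  A pollen assay that detects the ALT base at such a locus is
#' diagnostic for its target cultivar.
#'
#' Per locus the rule is: REF is the base homozygous in the largest number of
#' cultivars (a tie disqualifies the locus); ALT is the single other base
#' homozygous in at least one cultivar (none, or more than one such base,
#' disqualifies the locus).  Cultivars carrying exactly one copy of ALT are
#' recorded as heterozygous carriers; cultivars with a missing call are
#' flagged (their ALT status is unknown, not absent); cultivars whose call
#' contains a base outside \{REF, ALT\} are flagged as anomalous.  A locus
#' whose ALT base is homozygous in more than one cultivar is retained but
#' marked non-unique: its detections implicate the small set of homozygotes
#' rather than a single cultivar, and it does not count towards a cultivar's
#' identifiability in [validate_panel()].
#'
#' @param gm a [genotype_matrix()].
#' @return An object of class `panel_design`: a list with `loci` (one record
#'   per retained locus: `locus_id`, `ref`, `alt`, `target`, `hom_alt`,
#'   `het_carriers`, `missing`, `anomalies`, `unique`), `cultivars`,
#'   `dosage` (integer matrix of ALT-copy counts, `NA` where the genotype is
#'   missing), `excluded` (data frame of dropped loci with reasons) and
#'   multiplex group slots filled by [multiplex_groups()].
#' @seealso [multiplex_groups()], [validate_panel()], [export_panel()]
#' @export
find_private_alleles <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  loci <- list()
  excluded <- list()
  for (i in seq_along(gm$loci)) {
    lid <- gm$loci[i]
    calls <- gm$geno[i, ]
    rec <- .scan_locus(lid, calls, gm$cultivars)
    if (is.character(rec)) {
      excluded[[length(excluded) + 1L]] <- data.frame(locus = lid,
                                                      reason = rec)
    } else {
      loci[[lid]] <- rec
    }
  }
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(locus = character(0), reason = character(0))
  dosage <- ref_dosage <- matrix(NA_integer_, nrow = length(loci),
                                 ncol = length(gm$cultivars),
                                 dimnames = list(names(loci), gm$cultivars))
  for (lid in names(loci)) {
    dosage[lid, ] <- vapply(gm$geno[lid, ], .base_dosage, integer(1L),
                            base = loci[[lid]]$alt)
    ref_dosage[lid, ] <- vapply(gm$geno[lid, ], .base_dosage, integer(1L),
                                base = loci[[lid]]$ref)
  }
  pd <- structure(list(loci = loci, cultivars = gm$cultivars,
                       dosage = dosage, ref_dosage = ref_dosage,
                       excluded = excluded,
                       multiplex_groups_alt = NULL,
                       multiplex_groups_ref = NULL),
                  class = "panel_design")
  multiplex_groups(pd)
}

# classify one locus; returns a panel-locus record, or a character reason
# for exclusion
.scan_locus <- function(lid, calls, cultivars) {
  present <- !is.na(calls)
  if (!any(present)) return("all genotypes missing")
  hom_base <- ifelse(present & substr(calls, 1L, 1L) == substr(calls, 2L, 2L),
                     substr(calls, 1L, 1L), NA_character_)
  tab <- table(hom_base[!is.na(hom_base)])
  if (length(tab) == 0L) return("no homozygous genotype")
  ref <- names(tab)[tab == max(tab)]
  if (length(ref) > 1L) return("no predominant (REF) allele")
  cand <- setdiff(names(tab), ref)
  if (length(cand) == 0L) return("no private homozygous allele")
  if (length(cand) > 1L) return("multiple candidate alternative alleles")
  alt <- cand
  dos <- vapply(calls, .base_dosage, integer(1L), base = alt)
  hom_alt <- cultivars[!is.na(dos) & dos == 2L]
  het <- cultivars[!is.na(dos) & dos == 1L]
  miss <- cultivars[!present]
  outside <- vapply(calls, function(cl) {
    if (is.na(cl)) return(FALSE)
    any(!strsplit(cl, "")[[1L]] %in% c(ref, alt))
  }, logical(1L))
  anomalies <- cultivars[outside]
  list(locus_id = lid, ref = ref, alt = alt,
       target = hom_alt[1L],            # first homozygote in column order
       hom_alt = hom_alt, het_carriers = het, missing = miss,
       anomalies = anomalies, unique = length(hom_alt) == 1L)
}

#' Group panel loci by single-base-extension base
#'
#' Single-base-extension assays are multiplexed by the base that the
#' extension reaction adds, so panel loci are partitioned once by their ALT
#' base (the allele-detection assay) and once by their REF base (the
#' predominant-allele assay).
#'
#' @param pd a [find_private_alleles()] panel design with at least one locus.
#' @return `pd` with `multiplex_groups_alt` and `multiplex_groups_ref`
#'   filled: named lists of locus-id vectors, keyed by base.  The groups in
#'   each partition are disjoint and jointly cover all panel loci.
#' @export
multiplex_groups <- function(pd) {
  stopifnot(inherits(pd, "panel_design"))
  if (length(pd$loci) < 1L) stop("panel has no loci to group")
  ids <- names(pd$loci)
  alt <- vapply(pd$loci, `[[`, character(1L), "alt")
  ref <- vapply(pd$loci, `[[`, character(1L), "ref")
  pd$multiplex_groups_alt <- split(ids, alt)
  pd$multiplex_groups_ref <- split(ids, ref)
  pd
}

#' Validate a diagnostic panel against its genotype matrix
#'
#' Checks that every cultivar in the genotype matrix is identifiable, i.e.
#' has at least one locus at which it is the sole homozygous-ALT cultivar,
#' and collects per-locus warnings: heterozygous carriers of the ALT allele,
#' shared (non-unique) homozygotes, alleles outside \{REF, ALT\}, and
#' missing genotypes.
#'
#' @param pd a panel design derived from `gm`.
#' @param gm the [genotype_matrix()] the panel was derived from.
#' @return An object of class `panel_validation`: list with `cultivars`
#'   (data frame: cultivar, n_diagnostic, diagnostic_loci, n_shared_hom),
#'   `warnings` (data frame: locus, type, cultivars), `flagged_na`
#'   (loci with missing genotypes), `excluded`, and `pass` (`TRUE` iff every
#'   cultivar has >= 1 sole-homozygous-ALT locus).
#' @export
validate_panel <- function(pd, gm) {
  stopifnot(inherits(pd, "panel_design"), inherits(gm, "genotype_matrix"))
  cv <- gm$cultivars
  n_diag <- integer(length(cv)); names(n_diag) <- cv
  n_shared <- integer(length(cv)); names(n_shared) <- cv
  diag_loci <- stats::setNames(vector("list", length(cv)), cv)
  warn <- list()
  for (rec in pd$loci) {
    if (rec$unique) {
      n_diag[rec$target] <- n_diag[rec$target] + 1L
      diag_loci[[rec$target]] <- c(diag_loci[[rec$target]], rec$locus_id)
    } else {
      for (c in rec$hom_alt) n_shared[c] <- n_shared[c] + 1L
      warn[[length(warn) + 1L]] <- data.frame(
        locus = rec$locus_id, type = "shared_homozygous_alt",
        cultivars = paste(rec$hom_alt, collapse = ";"))
    }
    if (length(rec$het_carriers))
      warn[[length(warn) + 1L]] <- data.frame(
        locus = rec$locus_id, type = "het_carrier",
        cultivars = paste(rec$het_carriers, collapse = ";"))
    if (length(rec$anomalies))
      warn[[length(warn) + 1L]] <- data.frame(
        locus = rec$locus_id, type = "allele_outside_ref_alt",
        cultivars = paste(rec$anomalies, collapse = ";"))
  }
  warn <- if (length(warn)) do.call(rbind, warn) else
    data.frame(locus = character(0), type = character(0),
               cultivars = character(0))
  flagged_na <- unique(unlist(lapply(pd$loci, function(r)
    if (length(r$missing)) r$locus_id else NULL)))
  cultivar_df <- data.frame(
    cultivar = cv, n_diagnostic = unname(n_diag),
    diagnostic_loci = vapply(cv, function(c)
      paste(diag_loci[[c]], collapse = ";"), character(1L)),
    n_shared_hom = unname(n_shared))
  structure(list(cultivars = cultivar_df, warnings = warn,
                 flagged_na = flagged_na %||% character(0),
                 excluded = pd$excluded,
                 pass = all(n_diag >= 1L)),
            class = "panel_validation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a panel design to CSV
#'
#' @param pd a panel design with multiplex groups filled.
#' @param path output file path.
#' @param header_lines optional character vector of comment lines (prefixed
#'   `#`) written before the CSV header.
#' @return The exported data frame, invisibly.
#' @export
export_panel <- function(pd, path, header_lines = NULL) {
  stopifnot(inherits(pd, "panel_design"))
  alt_group <- ref_group <- character(length(pd$loci))
  df <- data.frame(
    locus_id = names(pd$loci),
    ref = vapply(pd$loci, `[[`, character(1L), "ref"),
    alt = vapply(pd$loci, `[[`, character(1L), "alt"),
    target = vapply(pd$loci, `[[`, character(1L), "target"),
    het_carriers = vapply(pd$loci, function(r)
      paste(r$het_carriers, collapse = ";"), character(1L)),
    missing = vapply(pd$loci, function(r)
      paste(r$missing, collapse = ";"), character(1L)),
    alt_group = vapply(pd$loci, `[[`, character(1L), "alt"),
    ref_group = vapply(pd$loci, `[[`, character(1L), "ref"),
    row.names = NULL)
  .write_csv_with_header(df, path, header_lines)
  invisible(df)
}

.write_csv_with_header <- function(df, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines))
    writeLines(paste0("# ", header_lines), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' @export
print.panel_design <- function(x, ...) {
  cat(sprintf("panel_design: %d diagnostic loci over %d cultivars\n",
              length(x$loci), length(x$cultivars)))
  if (nrow(x$excluded))
    cat(sprintf("excluded loci: %s\n",
                paste(x$excluded$locus, collapse = ", ")))
  if (!is.null(x$multiplex_groups_alt)) {
    sizes <- vapply(x$multiplex_groups_alt, length, integer(1L))
    cat("ALT extension groups:",
        paste(sprintf("%s(%d)", names(sizes), sizes), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
print.panel_validation <- function(x, ...) {
  cat(sprintf("panel validation: %s\n", if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("%d/%d cultivars identifiable by a sole-homozygous-ALT locus\n",
              sum(x$cultivars$n_diagnostic >= 1L), nrow(x$cultivars)))
  if (nrow(x$warnings)) {
    cat("warnings:\n")
    for (i in seq_len(nrow(x$warnings)))
      cat(sprintf("  locus %s: %s (%s)\n", x$warnings$locus[i],
                  x$warnings$type[i], x$warnings$cultivars[i]))
  }
  if (length(x$flagged_na))
    cat("loci with missing genotypes:",
        paste(x$flagged_na, collapse = ", "), "\n")
  if (nrow(x$excluded))
    cat("excluded:",
        paste(sprintf("%s (%s)", x$excluded$locus, x$excluded$reason),
              collapse = "; "), "\n")
  invisible(x)
}
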
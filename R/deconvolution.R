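#' Infer the cultivars contributing to a mixed pollen sample
#'
#' Given per-locus ALT-allele detections from one bee's pollen DNA and a
#' private-allele panel, works out which cultivars must be present
#' (`confirmed`), which minimal sets of cultivars equally explain the
#' remaining signal (`ambiguous_alternatives`), and which detections no
#' panel cultivar can explain (`unexplained_loci`).
#'
#' Candidate carriers of a fired locus are the homozygous-ALT cultivars, the
#' heterozygous carriers, and cultivars whose genotype there is missing
#' (unknown is not absent).  Explanations are scored as exact set covers of
#' the fired loci, ranked by:
#' \enumerate{
#'   \item dosage consistency -- an explanation is consistent when every
#'     member's full homozygous signature fired (a homozygote sheds full
#'     dosage at all its diagnostic loci, so partial signatures imply
#'     dropout) and every fired locus is covered homozygously, by a
#'     heterozygous carrier all of whose carried loci also fired (a
#'     heterozygote's loci share one dosage level and fire all-or-none for
#'     a common threshold), or by a missing-genotype cultivar;
#'   \item the number of fired loci lacking a full-dosage (homozygous)
#'     explanation, fewer first;
#'   \item fewer cultivars;
#'   \item fewer loci explained only through missing genotypes;
#'   \item cultivar name order.
#' }
#' Confirmation uses two monotone rules: a cultivar is confirmed when it is
#' the sole candidate at some fired locus (even if the rest of its
#' signature dropped out), or when its complete homozygous signature fired.
#' Removing a detection therefore never adds a confirmed cultivar.  The
#' ranked covers supply what confirmation cannot: loci not explained by
#' confirmed cultivars are covered by the best-tier explanations, whose
#' non-confirmed remainders are reported as `ambiguous_alternatives`
#' (minimum-cardinality covers when no dosage-consistent explanation
#' exists, as under dropout or noise).  Independent signal groups -- fired
#' loci whose candidate sets do not overlap -- are solved separately and
#' their alternatives combined.
#'
#' @param calls detections for one bee: either a character vector of loci
#'   with the ALT allele detected, a named logical vector (names = loci), or
#'   a data frame with columns `locus_id` and `alt_detected` (an `assay`
#'   column restricts rows to `"ALT"`).
#' @param pd a [find_private_alleles()] panel design.
#' @return An object of class `cultivar_presence`: list with `confirmed`,
#'   `ambiguous_alternatives` (list of cultivar sets, best first, disjoint
#'   from `confirmed`), `unexplained_loci`, `fired` (the ALT-detected loci)
#'   and `top` (confirmed plus the best-ranked alternative, i.e. the
#'   top-ranked full explanation).
#' @export
interpret_calls <- function(calls, pd) {
  stopifnot(inherits(pd, "panel_design"))
  fired <- .normalize_calls(calls)
  unknown <- setdiff(fired, names(pd$loci))
  if (length(unknown))
    stop("call for unknown locus: ", paste(unknown, collapse = ", "))
  dos <- pd$dosage
  # per-cultivar locus sets
  sig <- lapply(pd$cultivars, function(c)
    rownames(dos)[!is.na(dos[, c]) & dos[, c] == 2L])
  carried <- lapply(pd$cultivars, function(c)
    rownames(dos)[!is.na(dos[, c]) & dos[, c] >= 1L])
  names(sig) <- names(carried) <- pd$cultivars

  cand <- lapply(fired, function(L)
    pd$cultivars[is.na(dos[L, ]) | dos[L, ] >= 1L])
  names(cand) <- fired
  unexplained <- fired[vapply(cand, length, integer(1L)) == 0L]
  expl <- setdiff(fired, unexplained)
  clause1 <- unique(unlist(cand[vapply(cand, length, integer(1L)) == 1L]))

  if (length(expl) == 0L) {
    out <- list(confirmed = sort(clause1 %||% character(0)),
                ambiguous_alternatives = list(),
                unexplained_loci = unexplained, fired = fired)
    out$top <- out$confirmed
    return(structure(out, class = "cultivar_presence"))
  }

  # Loci whose candidate sets do not overlap are independent evidence and
  # are solved separately: ambiguity or dropout in one signal group must
  # not suppress confirmation in an unrelated one.
  comps <- .components(expl, cand)
  # confirmed = sole-explanation loci (clause 1) plus complete-signature
  # cultivars (clause 2: every diagnostic locus fired).  Both clauses are
  # monotone: removing a detection can only shrink the confirmed set.
  clause2 <- pd$cultivars[vapply(pd$cultivars, function(c)
    length(sig[[c]]) > 0L && all(sig[[c]] %in% fired), logical(1L))]
  confirmed <- union(clause1, clause2)
  residuals <- list()
  for (loci_c in comps) {
    U <- sort(unique(unlist(cand[loci_c])))
    covers <- .enumerate_covers(U, loci_c, dos)
    keys <- lapply(covers, .cover_key, fired = fired, expl = loci_c,
                   dos = dos, sig = sig, carried = carried)
    ord <- order(vapply(keys, `[[`, numeric(1L), "inconsistent"),
                 vapply(keys, `[[`, numeric(1L), "k2"),
                 vapply(keys, `[[`, numeric(1L), "k3"),
                 vapply(keys, `[[`, numeric(1L), "k4"),
                 vapply(keys, `[[`, character(1L), "k5"))
    covers <- covers[ord]; keys <- keys[ord]
    best <- keys[[1L]]
    if (best$inconsistent == 0) {
      in_tier <- vapply(keys, function(k)
        k$inconsistent == 0 && k$k2 == best$k2 && k$k3 == best$k3 &&
          k$k4 == best$k4, logical(1L))
      tier <- covers[in_tier]
    } else {
      m <- min(vapply(keys, `[[`, numeric(1L), "k3"))
      tier <- covers[vapply(keys, function(k) k$k3 == m, logical(1L))]
    }
    residuals[[length(residuals) + 1L]] <- tier
  }
  alts <- .combine_residuals(residuals, confirmed)
  out <- list(confirmed = sort(confirmed %||% character(0)),
              ambiguous_alternatives = alts,
              unexplained_loci = unexplained, fired = fired)
  out$top <- sort(union(out$confirmed,
                        if (length(alts)) alts[[1L]] else character(0)))
  structure(out, class = "cultivar_presence")
}

.normalize_calls <- function(calls) {
  if (is.data.frame(calls)) {
    df <- calls
    if ("assay" %in% names(df)) df <- df[df$assay == "ALT", , drop = FALSE]
    if (!all(c("locus_id", "alt_detected") %in% names(df)) &&
        !all(c("locus_id", "detected") %in% names(df)))
      stop("calls data frame needs columns locus_id and alt_detected/detected")
    det <- if ("alt_detected" %in% names(df)) df$alt_detected else df$detected
    return(unique(as.character(df$locus_id[as.logical(as.numeric(det))])))
  }
  if (is.logical(calls)) {
    if (is.null(names(calls))) stop("logical calls must be named by locus")
    return(names(calls)[calls])
  }
  unique(as.character(calls))
}

# connected components of fired loci under shared candidate cultivars
.components <- function(expl, cand) {
  comps <- lapply(expl, function(L) L)
  sets <- lapply(expl, function(L) cand[[L]])
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < length(comps)) {
      j <- i + 1L
      while (j <= length(comps)) {
        if (length(intersect(sets[[i]], sets[[j]]))) {
          comps[[i]] <- c(comps[[i]], comps[[j]])
          sets[[i]] <- union(sets[[i]], sets[[j]])
          comps[[j]] <- NULL; sets[[j]] <- NULL
          merged <- TRUE
        } else j <- j + 1L
      }
      i <- i + 1L
    }
    if (!merged) break
  }
  comps
}

# residuals: per component, its tier of best covers.  Alternatives are
# combinations of one cover per component, with confirmed cultivars
# removed; capped to keep degenerate noisy inputs bounded.
.combine_residuals <- function(residuals, confirmed, cap = 64L) {
  res <- lapply(residuals, function(tier) {
    a <- unique(lapply(tier, function(S) sort(setdiff(S, confirmed))))
    a[order(vapply(a, length, integer(1L)),
            vapply(a, paste, character(1L), collapse = "|"))]
  })
  res <- res[vapply(res, function(a)
    any(vapply(a, length, integer(1L)) > 0L), logical(1L))]
  if (length(res) == 0L) return(list())
  combos <- list(character(0))
  for (a in res) {
    combos <- unlist(lapply(combos, function(base)
      lapply(a, function(s) sort(union(base, s)))), recursive = FALSE)
    if (length(combos) > cap) combos <- combos[seq_len(cap)]
  }
  unique(combos[vapply(combos, length, integer(1L)) > 0L])
}

# all covers of the fired loci `expl` by subsets of U
.enumerate_covers <- function(U, expl, dos) {
  nu <- length(U)
  # coverage matrix: TRUE if cultivar can explain locus (dosage >= 1 or NA)
  covm <- vapply(U, function(c) is.na(dos[expl, c]) | dos[expl, c] >= 1L,
                 logical(length(expl)))
  covm <- matrix(covm, nrow = length(expl), dimnames = list(expl, U))
  covers <- list()
  for (mask in seq_len(2^nu - 1L)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(nu) - 1L)))
    sub <- covm[, sel, drop = FALSE]
    if (!all(rowSums(sub) > 0L)) next
    # every member must explain at least one fired locus (no freeloaders);
    # genuinely redundant members are allowed -- a cultivar whose loci are
    # also covered by a het carrier may still be present -- and are ranked
    # out by the cover keys instead
    if (!all(colSums(sub) > 0L)) next
    covers[[length(covers) + 1L]] <- U[sel]
  }
  covers
}

.cover_key <- function(S, fired, expl, dos, sig, carried) {
  sig_ok <- all(vapply(S, function(e) all(sig[[e]] %in% fired), logical(1L)))
  hom_cov <- vapply(expl, function(L)
    any(!is.na(dos[L, S]) & dos[L, S] == 2L), logical(1L))
  het_cons <- vapply(expl, function(L)
    any(vapply(S, function(e)
      !is.na(dos[L, e]) && dos[L, e] == 1L && all(carried[[e]] %in% fired),
      logical(1L))), logical(1L))
  miss_cov <- vapply(expl, function(L) any(is.na(dos[L, S])), logical(1L))
  any_dosage <- vapply(expl, function(L)
    any(!is.na(dos[L, S]) & dos[L, S] >= 1L), logical(1L))
  consistent <- sig_ok && all(hom_cov | het_cons | miss_cov)
  list(inconsistent = as.numeric(!consistent),
       k2 = sum(!hom_cov),
       k3 = length(S),
       k4 = sum(!any_dosage),
       k5 = paste(sort(S), collapse = "|"))
}

#' @export
print.cultivar_presence <- function(x, ...) {
  cat("cultivar presence\n")
  cat("  ALT detections:", if (length(x$fired))
    paste(x$fired, collapse = ", ") else "(none)", "\n")
  cat("  confirmed:", if (length(x$confirmed))
    paste(x$confirmed, collapse = ", ") else "(none)", "\n")
  if (length(x$ambiguous_alternatives))
    cat("  alternatives:",
        paste(vapply(x$ambiguous_alternatives, paste, character(1L),
                     collapse = "+"), collapse = " | "), "\n")
  if (length(x$unexplained_loci))
    cat("  unexplained loci:",
        paste(x$unexplained_loci, collapse = ", "), "\n")
  invisible(x)
}

#' Classify a bee's cross-pollination capability
#'
#' A bee carries self-pollen when its host cultivar is confirmed in the
#' pollen load, and cross-pollen when any other cultivar is confirmed --
#' or, under the default `"any"` ambiguity policy, when every alternative
#' explanation of the remaining signal involves a non-host cultivar.  Bees
#' carrying any cross-pollen can cross-pollinate a self-incompatible crop
#' (score 1); bees carrying exclusively self-pollen cannot (score 0); bees
#' with no detectable pollen signal are undetermined (score `NA`).
#'
#' @param presence a [interpret_calls()] result.
#' @param host_cultivar the cultivar of the tree the bee was collected from.
#' @param pd the panel design (for host-name validation).
#' @param ambiguity `"any"` (default: cross-pollen is counted when all
#'   minimal explanations include a non-host cultivar) or `"confirmed"`
#'   (cross-pollen only from confirmed cultivars).
#' @return An object of class `bee_classification`: list with `category`
#'   (`"CROSS_ONLY"`, `"MIXED"`, `"SELF_ONLY"` or `"UNDETERMINED"`), `score`
#'   (1, 1, 0, `NA` respectively), `cross_cultivars` (confirmed non-host
#'   cultivars) and `ambiguous_cross` (whether the cross call rests on
#'   ambiguous alternatives only).
#' @export
classify_bee <- function(presence, host_cultivar, pd,
                         ambiguity = c("any", "confirmed")) {
  stopifnot(inherits(presence, "cultivar_presence"),
            inherits(pd, "panel_design"))
  ambiguity <- match.arg(ambiguity)
  if (!host_cultivar %in% pd$cultivars)
    stop("unknown host cultivar: ", host_cultivar)
  self <- host_cultivar %in% presence$confirmed
  cross_conf <- setdiff(presence$confirmed, host_cultivar)
  amb <- presence$ambiguous_alternatives
  cross_amb <- ambiguity == "any" && length(amb) > 0L &&
    all(vapply(amb, function(s)
      length(setdiff(s, host_cultivar)) > 0L, logical(1L)))
  cross <- length(cross_conf) > 0L || cross_amb
  category <- if (cross && self) "MIXED" else if (cross) "CROSS_ONLY"
    else if (self) "SELF_ONLY" else "UNDETERMINED"
  score <- switch(category, CROSS_ONLY = 1L, MIXED = 1L, SELF_ONLY = 0L,
                  UNDETERMINED = NA_integer_)
  structure(list(category = category, score = score,
                 cross_cultivars = cross_conf,
                 ambiguous_cross = length(cross_conf) == 0L && cross_amb),
            class = "bee_classification")
}

#' @export
print.bee_classification <- function(x, ...) {
  cat(sprintf("bee classification: %s (score %s)\n", x$category,
              ifelse(is.na(x$score), "NA", x$score)))
  if (length(x$cross_cultivars))
    cat("  cross-pollen cultivars:",
        paste(x$cross_cultivars, collapse = ", "), "\n")
  invisible(x)
}

#' Deconvolve and classify a whole dataset of bees
#'
#' @param calls long-format call table: columns `bee_id`, `locus_id`,
#'   `assay` (`"ALT"`/`"REF"`; optional, `"ALT"` assumed), `detected`
#'   (0/1 or logical).
#' @param pd a panel design.
#' @param metadata bee metadata: columns `bee_id`, `host_cultivar`, and
#'   optionally `transect_id`, `orchard_type`, `row_index`, `distance_m`
#'   (carried through to the output).
#' @param ambiguity passed to [classify_bee()].
#' @return A data frame with one row per bee: the metadata columns plus
#'   `category`, `score`, `confirmed` (semicolon-joined), `ambiguous`
#'   (whether alternatives remained), `n_alt_detections`.  The number of
#'   UNDETERMINED bees (flagged for exclusion from downstream statistics)
#'   is reported in attribute `n_undetermined`.
#' @export
deconvolve_dataset <- function(calls, pd, metadata,
                               ambiguity = c("any", "confirmed")) {
  stopifnot(inherits(pd, "panel_design"))
  ambiguity <- match.arg(ambiguity)
  if (nrow(calls) == 0L) {
    out <- metadata[0, , drop = FALSE]
    out$category <- character(0); out$score <- integer(0)
    out$confirmed <- character(0); out$ambiguous <- logical(0)
    out$n_alt_detections <- integer(0)
    attr(out, "n_undetermined") <- 0L
    return(out)
  }
  bees <- unique(as.character(calls$bee_id))
  missing_host <- setdiff(bees, as.character(metadata$bee_id))
  if (length(missing_host))
    stop("bee with calls but no host metadata: ",
         paste(missing_host, collapse = ", "))
  md <- metadata[match(bees, as.character(metadata$bee_id)), , drop = FALSE]
  rows <- lapply(seq_along(bees), function(i) {
    b <- bees[i]
    pres <- interpret_calls(calls[calls$bee_id == b, , drop = FALSE], pd)
    cls <- classify_bee(pres, as.character(md$host_cultivar[i]), pd,
                        ambiguity = ambiguity)
    data.frame(category = cls$category, score = cls$score,
               confirmed = paste(pres$confirmed, collapse = ";"),
               ambiguous = length(pres$ambiguous_alternatives) > 0L,
               n_alt_detections = length(pres$fired))
  })
  out <- cbind(md, do.call(rbind, rows))
  rownames(out) <- NULL
  attr(out, "n_undetermined") <- sum(out$category == "UNDETERMINED")
  out
}

#' Read a long-format allele-call CSV
#'
#' Expects columns `bee_id`, `locus_id`, `assay` (`ALT`/`REF`) and
#' `detected` (0/1).  Lines starting with `#` are ignored.
#' @param path file path.
#' @return A data frame.
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) stop("calls file not found: ", path)
  utils::read.csv(path, comment.char = "#", colClasses = c(
    bee_id = "character", locus_id = "character"))
}

#' Read a bee metadata CSV
#'
#' Expects columns `bee_id`, `host_cultivar` and optionally `transect_id`,
#' `orchard_type`, `row_index`, `distance_m`.  Lines starting with `#` are
#' ignored.
#' @param path file path.
#' @return A data frame.
#' @export
read_bee_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  utils::read.csv(path, comment.char = "#",
                  colClasses = c(bee_id = "character"))
}
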
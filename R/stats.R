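#' Per-row pollen-carriage proportions
#'
#' For every orchard type and row distance, tabulates the percentage of
#' included bees carrying exclusively cross-pollen, both cross- and
#' self-pollen, and exclusively self-pollen, plus the percentage carrying
#' any cross-pollen (CROSS_ONLY + MIXED).  UNDETERMINED bees (no pollen DNA
#' signal) are excluded and counted separately.  Per-transect percentages
#' and their across-transect mean and standard error are also returned.
#'
#' @param records bee-level data frame with columns `orchard_type`,
#'   `row_index`, `transect_id` and `category` (as produced by
#'   [deconvolve_dataset()]).
#' @return An object of class `pollen_proportions`: list with `cells` (one
#'   row per orchard x row), `transects` (one row per orchard x row x
#'   transect), `transect_summary` (across-transect mean +/- s.e. of the
#'   carrying-cross percentage) and `n_excluded`.
#' @export
summarize_proportions <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    stop("no bee records to summarize")
  inc <- records[records$category != "UNDETERMINED", , drop = FALSE]
  if (nrow(inc) == 0L) stop("no included bees (all UNDETERMINED)")
  pct <- function(df) {
    n <- nrow(df)
    co <- 100 * sum(df$category == "CROSS_ONLY") / n
    mx <- 100 * sum(df$category == "MIXED") / n
    so <- 100 * sum(df$category == "SELF_ONLY") / n
    data.frame(n = n, pct_cross_only = co, pct_mixed = mx,
               pct_self_only = so, pct_carrying_cross = co + mx)
  }
  key <- interaction(inc$orchard_type, inc$row_index, drop = TRUE)
  cells <- do.call(rbind, lapply(split(inc, key), function(df)
    cbind(data.frame(orchard_type = df$orchard_type[1L],
                     row_index = df$row_index[1L]), pct(df))))
  cells <- cells[order(cells$orchard_type, cells$row_index), ]
  tkey <- interaction(inc$orchard_type, inc$row_index, inc$transect_id,
                      drop = TRUE)
  transects <- do.call(rbind, lapply(split(inc, tkey), function(df)
    cbind(data.frame(orchard_type = df$orchard_type[1L],
                     row_index = df$row_index[1L],
                     transect_id = df$transect_id[1L]), pct(df))))
  transects <- transects[order(transects$orchard_type, transects$row_index,
                               transects$transect_id), ]
  tsum <- do.call(rbind, lapply(
    split(transects, interaction(transects$orchard_type,
                                 transects$row_index, drop = TRUE)),
    function(df) data.frame(
      orchard_type = df$orchard_type[1L], row_index = df$row_index[1L],
      n_transects = nrow(df),
      mean_pct_carrying_cross = mean(df$pct_carrying_cross),
      se_pct_carrying_cross = stats::sd(df$pct_carrying_cross) /
        sqrt(nrow(df)))))
  rownames(cells) <- rownames(transects) <- rownames(tsum) <- NULL
  structure(list(cells = cells, transects = transects,
                 transect_summary = tsum,
                 n_excluded = nrow(records) - nrow(inc)),
            class = "pollen_proportions")
}

#' @export
print.pollen_proportions <- function(x, digits = 1L, ...) {
  cat("pollen carriage by orchard and row\n")
  df <- x$cells
  df[4:7] <- round(df[4:7], digits)
  print(df, row.names = FALSE)
  if (x$n_excluded > 0L)
    cat(sprintf("(%d UNDETERMINED bees excluded)\n", x$n_excluded))
  invisible(x)
}

#' Stacked-bar plot of carriage categories by row
#' @param x a [summarize_proportions()] result.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.pollen_proportions <- function(x, ...) {
  for (ot in unique(x$cells$orchard_type)) {
    df <- x$cells[x$cells$orchard_type == ot, ]
    m <- t(as.matrix(df[, c("pct_cross_only", "pct_mixed",
                            "pct_self_only")]))
    colnames(m) <- paste("row", df$row_index)
    graphics::barplot(m, main = paste(ot, "orchard"),
                      ylab = "% of honeybees",
                      legend.text = c("cross only", "cross + self",
                                      "self only"), ...)
  }
  invisible(x)
}

#' Composition of the cross-pollen carried
#'
#' Among bees that carry any cross-pollen, reports per orchard type and host
#' cultivar the percentage carrying exactly one cross-pollen cultivar, and
#' how often each cross-pollen cultivar occurs (a bee carrying k cross
#' cultivars contributes to k cultivar rows; percentages are of
#' cross-carrying bees).
#'
#' @param records bee-level data frame with `orchard_type`, `host_cultivar`,
#'   `score` and `confirmed` (semicolon-joined cultivars) columns.
#' @return An object of class `cross_sources`: list with `groups` (per
#'   orchard x host: n cross-carrying bees, % with one cross cultivar),
#'   `cultivars` (per orchard x host x cross cultivar: count and % of
#'   cross-carrying bees) and `n_cross_bees`.  Empty tables (with a notice
#'   attribute) when no bee carries cross-pollen.
#' @export
summarize_cross_sources <- function(records) {
  stopifnot(nrow(records) >= 1L)
  cross_sets <- lapply(seq_len(nrow(records)), function(i)
    setdiff(strsplit(records$confirmed[i] %||% "", ";")[[1L]],
            records$host_cultivar[i]))
  has_cross <- !is.na(records$score) & records$score == 1L &
    vapply(cross_sets, length, integer(1L)) > 0L
  if (!any(has_cross)) {
    out <- structure(list(groups = data.frame(), cultivars = data.frame(),
                          n_cross_bees = 0L), class = "cross_sources")
    attr(out, "notice") <- "no cross-carrying bees"
    message("no cross-carrying bees")
    return(out)
  }
  df <- records[has_cross, , drop = FALSE]
  sets <- cross_sets[has_cross]
  key <- interaction(df$orchard_type, df$host_cultivar, drop = TRUE)
  groups <- list(); cultivars <- list()
  for (g in levels(key)) {
    idx <- which(key == g)
    n <- length(idx)
    one <- sum(vapply(sets[idx], length, integer(1L)) == 1L)
    groups[[g]] <- data.frame(
      orchard_type = df$orchard_type[idx[1L]],
      host_cultivar = df$host_cultivar[idx[1L]],
      n_cross_bees = n, pct_one_cultivar = 100 * one / n)
    tab <- table(unlist(sets[idx]))
    cultivars[[g]] <- data.frame(
      orchard_type = df$orchard_type[idx[1L]],
      host_cultivar = df$host_cultivar[idx[1L]],
      cross_cultivar = names(tab), n_bees = as.integer(tab),
      pct_of_cross_bees = 100 * as.integer(tab) / n, row.names = NULL)
  }
  structure(list(groups = do.call(rbind, c(groups, make.row.names = FALSE)),
                 cultivars = do.call(rbind, c(cultivars,
                                              make.row.names = FALSE)),
                 n_cross_bees = nrow(df)),
            class = "cross_sources")
}

#' @export
print.cross_sources <- function(x, ...) {
  cat(sprintf("cross-pollen sources (%d cross-carrying bees)\n",
              x$n_cross_bees))
  if (nrow(x$groups)) { print(x$groups, row.names = FALSE)
    print(x$cultivars, row.names = FALSE) }
  invisible(x)
}

#' Binomial mixed model for cross-pollen carriage
#'
#' Fits the probability that a bee carries cross-pollen (score 1 vs 0) as a
#' binomial-logit GLMM with fixed effects for distance from a cross-pollen
#' source, orchard type (WIDE as reference) and their interaction, and a
#' random intercept for the sampling transect, integrated by adaptive
#' Gauss-Hermite quadrature (`nAGQ` nodes; `nAGQ = 1` is the Laplace
#' approximation).  UNDETERMINED bees are excluded.  For a single-orchard
#' dataset the orchard terms are dropped automatically.  With
#' `random = FALSE` the transect intercept is constrained to zero and an
#' ordinary logistic regression is fitted.
#'
#' @param records bee-level data frame with `score`, `row_index`,
#'   `distance_m`, `orchard_type`, `transect_id`.
#' @param distance_unit `"rows"` (the default: the row index, matching
#'   distance measured in number of rows), `"meters"`, or `"min_rows"`
#'   (rows to the *nearest* different-cultivar block on either side, so the
#'   last row of a narrow block is recoded by its closer neighbour).
#' @param block_rows named vector giving the host-block row count per
#'   orchard type, used only by `"min_rows"`.
#' @param interaction include the distance x orchard interaction (ignored
#'   for single-orchard data).
#' @param random fit the transect random intercept (needs >= 2 transects).
#' @param nAGQ number of adaptive Gauss-Hermite quadrature nodes.
#' @return An object of class `pollen_glmm`: list with `coefficients`
#'   (term, estimate, se, z, p on the log-odds scale), `sigma_transect`
#'   (random-intercept SD), `loglik`, `n_bees`, `n_transects`,
#'   `n_excluded`, `converged`, `degenerate`, `engine` and `fit` (the
#'   underlying lme4/glm object).
#' @export
fit_glmm <- function(records, distance_unit = c("rows", "meters",
                                                "min_rows"),
                     block_rows = c(WIDE = 42, NARROW = 5),
                     interaction = TRUE, random = TRUE, nAGQ = 10L) {
  distance_unit <- match.arg(distance_unit)
  d <- records[!is.na(records$score), , drop = FALSE]
  if (nrow(d) == 0L) stop("no included bees")
  d$score <- as.integer(d$score)
  if (!all(d$score %in% c(0L, 1L))) stop("scores must be 0/1")
  d$distance <- switch(distance_unit,
    rows = as.numeric(d$row_index),
    meters = as.numeric(d$distance_m),
    min_rows = {
      br <- block_rows[as.character(d$orchard_type)]
      pmin(as.numeric(d$row_index), br - as.numeric(d$row_index) + 1)
    })
  n_orchard <- length(unique(d$orchard_type))
  n_transects <- length(unique(d$transect_id))
  out <- list(n_bees = nrow(d), n_transects = n_transects,
              n_excluded = nrow(records) - nrow(d),
              distance_unit = distance_unit,
              degenerate = FALSE, converged = FALSE)
  if (stats::var(d$score) == 0) {
    warning("degenerate data: all scores identical (complete separation)")
    out$degenerate <- TRUE
    out$coefficients <- data.frame(term = character(0))
    out$sigma_transect <- NA_real_
    class(out) <- "pollen_glmm"
    return(out)
  }
  rhs <- "distance"
  if (n_orchard > 1L) {
    d$orchard <- stats::relevel(factor(as.character(d$orchard_type)),
                                ref = "WIDE")
    rhs <- if (interaction) "distance * orchard" else "distance + orchard"
  }
  if (random && n_transects < 2L) {
    warning("fewer than 2 transects; dropping the random intercept")
    random <- FALSE
  }
  if (random) {
    fml <- stats::as.formula(paste("score ~", rhs, "+ (1 | transect_id)"))
    fit <- lme4::glmer(fml, data = d, family = stats::binomial(),
                       nAGQ = as.integer(nAGQ))
    sm <- summary(fit)$coefficients
    out$sigma_transect <- sqrt(unname(lme4::VarCorr(fit)$transect_id[1L]))
    out$loglik <- as.numeric(stats::logLik(fit))
    msgs <- fit@optinfo$conv$lme4$messages
    out$converged <- is.null(msgs) ||
      !any(grepl("failed to converge", unlist(msgs), ignore.case = TRUE))
    out$engine <- "glmer"
  } else {
    fml <- stats::as.formula(paste("score ~", rhs))
    fit <- stats::glm(fml, data = d, family = stats::binomial())
    sm <- summary(fit)$coefficients
    out$sigma_transect <- 0
    out$loglik <- as.numeric(stats::logLik(fit))
    out$converged <- fit$converged
    out$engine <- "glm"
  }
  est <- sm[, 1L]; se <- sm[, 2L]
  if (any(abs(est[-1L]) > 8) || any(se > 15)) {
    warning("possible separation: extreme coefficient or standard error; ",
            "interpret the flagged fit with care")
    out$separation_flag <- TRUE
  }
  z <- est / se
  out$coefficients <- data.frame(
    term = rownames(sm), estimate = unname(est), se = unname(se),
    z = unname(z), p = unname(2 * stats::pnorm(-abs(z))), row.names = NULL)
  out$fit <- fit
  out$data <- d
  class(out) <- "pollen_glmm"
  out
}

#' @export
print.pollen_glmm <- function(x, digits = 4L, ...) {
  cat(sprintf(
    "binomial GLMM for cross-pollen carriage (%s; %d bees, %d transects)\n",
    x$engine %||% "unfitted", x$n_bees, x$n_transects))
  if (x$degenerate) {
    cat("degenerate fit: all scores identical\n")
    return(invisible(x))
  }
  df <- x$coefficients
  df[-1L] <- lapply(df[-1L], signif, digits = digits)
  print(df, row.names = FALSE)
  cat(sprintf("transect random-intercept SD: %.4f%s\n", x$sigma_transect,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  invisible(x)
}

#' @export
summary.pollen_glmm <- function(object, ...) { print(object, ...) }

#' @export
coef.pollen_glmm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Report distance and orchard effects at a significance level
#'
#' @param fit a converged [fit_glmm()] result.
#' @param alpha significance level in (0, 1); default 0.05.
#' @param path optional CSV output path.
#' @return An object of class `distance_effect_report`: the coefficient
#'   table with a `significant` column, plus `alpha`.
#' @export
distance_effect_report <- function(fit, alpha = 0.05, path = NULL) {
  stopifnot(inherits(fit, "pollen_glmm"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be a probability strictly between 0 and 1")
  if (fit$degenerate || !fit$converged)
    stop("refusing to report on an unconverged or degenerate fit")
  df <- fit$coefficients
  df$significant <- df$p < alpha
  out <- structure(list(table = df, alpha = alpha,
                        sigma_transect = fit$sigma_transect),
                   class = "distance_effect_report")
  if (!is.null(path)) .write_csv_with_header(df, path)
  out
}

#' @export
print.distance_effect_report <- function(x, ...) {
  cat(sprintf("effects on cross-pollen carriage (alpha = %g)\n", x$alpha))
  for (i in seq_len(nrow(x$table))) {
    r <- x$table[i, ]
    if (r$term == "(Intercept)") next
    cat(sprintf("  %s: estimate = %.3f, s.e. = %.3f, p = %.3g -> %s\n",
                r$term, r$estimate, r$se, r$p,
                if (r$significant) "significant" else "not significant"))
  }
  invisible(x)
}
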
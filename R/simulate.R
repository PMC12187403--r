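#' Build an orchard layout
#'
#' Lays out contiguous single-cultivar row blocks on a rectangular grid and
#' optionally replaces individual trees with off-type cultivars (e.g.
#' storm-damage replacements), which act as covert cross-pollen sources
#' inside a block.
#'
#' @param config a list with elements `type` (`"WIDE"`/`"NARROW"`), `blocks`
#'   (list of `list(cultivar=, n_rows=)` in planting order), `trees_per_row`,
#'   `row_spacing_m`, `tree_spacing_m`, `offtype_rate` (per-tree replacement
#'   probability) and `offtype_pool` (cultivars replacements are drawn
#'   from).  See [orchard_preset()].
#' @param cultivars optional character vector of admissible cultivar names
#'   (e.g. a panel's); unknown cultivars raise an error.
#' @param seed integer seed for the off-type draw.
#' @return An object of class `orchard_layout`: list with `type`, `grid`
#'   (character matrix rows x tree positions of actual cultivars), `planted`
#'   (the same before off-type replacement), `blocks` (data frame with
#'   `cultivar`, `n_rows`, `row_start`, `row_end`), spacings and the
#'   off-type settings.
#' @export
build_orchard <- function(config, cultivars = NULL, seed = 1L) {
  bl <- config$blocks
  if (is.null(bl) || length(bl) == 0L) stop("orchard config has no blocks")
  cvs <- vapply(bl, function(b) as.character(b$cultivar), character(1L))
  nr <- vapply(bl, function(b) as.integer(b$n_rows), integer(1L))
  if (any(nr < 1L)) stop("each block needs n_rows >= 1")
  tpr <- as.integer(config$trees_per_row %||% 50L)
  if (tpr < 1L) stop("trees_per_row must be >= 1")
  rate <- as.numeric(config$offtype_rate %||% 0)
  pool <- as.character(config$offtype_pool %||% character(0))
  if (rate < 0 || rate > 1) stop("offtype_rate must be in [0, 1]")
  if (rate > 0 && length(pool) == 0L)
    stop("offtype_rate > 0 needs a non-empty offtype_pool")
  if (!is.null(cultivars)) {
    bad <- setdiff(c(cvs, pool), cultivars)
    if (length(bad)) stop("unknown cultivar: ", paste(bad, collapse = ", "))
  }
  row_end <- cumsum(nr)
  row_start <- row_end - nr + 1L
  planted <- matrix(rep(rep(cvs, times = nr), tpr), nrow = sum(nr))
  grid <- planted
  if (rate > 0) {
    set.seed(as.integer(seed))
    hit <- matrix(stats::runif(length(grid)) < rate, nrow = nrow(grid))
    grid[hit] <- sample(pool, sum(hit), replace = TRUE)
  }
  structure(list(type = toupper(as.character(config$type %||% "WIDE")),
                 grid = grid, planted = planted,
                 blocks = data.frame(cultivar = cvs, n_rows = nr,
                                     row_start = row_start,
                                     row_end = row_end),
                 trees_per_row = tpr,
                 row_spacing_m = as.numeric(config$row_spacing_m %||% 8),
                 tree_spacing_m = as.numeric(config$tree_spacing_m %||% 4),
                 offtype_rate = rate, offtype_pool = pool),
            class = "orchard_layout")
}

#' @export
print.orchard_layout <- function(x, ...) {
  cat(sprintf("orchard_layout (%s): %d rows x %d trees; %s\n", x$type,
              nrow(x$grid), x$trees_per_row,
              paste(sprintf("%s(%d rows)", x$blocks$cultivar,
                            x$blocks$n_rows), collapse = " | ")))
  n_off <- sum(x$grid != x$planted)
  if (n_off) cat(sprintf("off-type trees: %d (rate %.3f)\n", n_off,
                         x$offtype_rate))
  invisible(x)
}

#' Built-in orchard and study presets
#'
#' `"wide"`: two large blocks, 42 rows of '816' next to 48 rows of 'Daddow',
#' 8 m between rows, 4 m between trees; transects at rows 1, 2, 3 and 11
#' from the block boundary.  `"narrow"`: five 5-row blocks (A203, 842, 816,
#' A4, 741), 10 m between rows, 2 m between trees; transects at rows 1-4.
#' `"wide_demo"` is the wide layout with within-row off-type trees
#' (rate 0.08, drawn from 741 and 849), representing an orchard whose
#' single-cultivar blocks hide replacement trees.
#'
#' @param name `"wide"`, `"narrow"` or `"wide_demo"`.
#' @return A full study config list (orchard, transects, foraging, assay)
#'   suitable for [generate_study()].
#' @export
orchard_preset <- function(name = c("wide", "narrow", "wide_demo")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(
    c(wide = "wide_block", narrow = "narrow_block",
      wide_demo = "wide_demo")[[name]], ".yaml"), package = "pollenpanel")
  read_study_config(path)
}

#' Read and validate a study configuration
#'
#' @param path a YAML file with sections `orchard`, `transects`, `foraging`
#'   and `assay` (see the packaged presets under `extdata/`).
#' @return The config list with defaults filled in.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (sec in c("orchard", "transects"))
    if (is.null(cfg[[sec]]))
      stop("config is missing required section: ", sec)
  f <- cfg$foraging %||% list()
  cfg$foraging <- list(
    p_row_switch = as.numeric(f$p_row_switch %||% 0.1),
    n_visits = as.integer(f$n_visits %||% 30L),
    carryover_retention = as.numeric(f$carryover_retention %||% 0.7),
    pickup_grains = as.numeric(f$pickup_grains %||% 1),
    capture_visit = f$capture_visit %||% "uniform",
    capture_pickup = isTRUE(f$capture_pickup))
  a <- cfg$assay %||% list()
  cfg$assay <- list(theta_detect = as.numeric(a$theta_detect %||% 0.05),
                    fn_rate = as.numeric(a$fn_rate %||% 0),
                    fp_rate = as.numeric(a$fp_rate %||% 0))
  with(cfg$foraging, {
    if (p_row_switch < 0 || p_row_switch > 1)
      stop("invalid config field: foraging$p_row_switch")
    if (n_visits < 1L) stop("invalid config field: foraging$n_visits")
    if (carryover_retention < 0 || carryover_retention >= 1)
      stop("invalid config field: foraging$carryover_retention")
  })
  with(cfg$assay, {
    if (theta_detect < 0 || theta_detect > 1)
      stop("invalid config field: assay$theta_detect")
    if (fn_rate < 0 || fn_rate > 1 || fp_rate < 0 || fp_rate > 1)
      stop("invalid config field: assay$fn_rate/fp_rate")
  })
  tr <- cfg$transects
  if (is.null(tr$rows) || length(tr$rows) < 1L)
    stop("invalid config field: transects$rows")
  if (is.null(tr$bees_per_point) || as.integer(tr$bees_per_point) < 1L)
    stop("invalid config field: transects$bees_per_point")
  if (is.null(tr$hosts)) stop("invalid config field: transects$hosts")
  cfg
}

#' Simulate one foraging trip
#'
#' A discrete random walk over trees: at each move the bee switches to an
#' adjacent row with probability `p_row_switch`, otherwise continues along
#' its row in a persistent direction (reflecting at row ends).  At each
#' visited tree the existing pollen load is decayed by the carryover
#' retention `rho` and `pickup_grains` of that tree's cultivar are added,
#' so after each visit `total = rho * previous + pickup_grains`.
#'
#' @param layout an [build_orchard()] layout.
#' @param fp foraging parameters: list with `p_row_switch`, `n_visits`,
#'   `carryover_retention`, `pickup_grains`, `capture_visit` (an index or
#'   `"uniform"`), `capture_pickup` (does the capture visit add pickup?
#'   default `TRUE`).
#' @param start integer vector `c(row, position)` of the first tree.
#' @param seed integer seed; identical seeds give identical trips.
#' @return An object of class `pollen_load`: list with `grains` (named
#'   cultivar totals at capture), `capture_visit`, and `visits` (data frame
#'   `row`, `pos`, `cultivar` of the trees visited up to capture).
#' @export
simulate_trip <- function(layout, fp, start, seed = 1L) {
  stopifnot(inherits(layout, "orchard_layout"))
  fp <- .fill_foraging(fp)
  nrows <- nrow(layout$grid); npos <- layout$trees_per_row
  if (start[1L] < 1L || start[1L] > nrows || start[2L] < 1L ||
      start[2L] > npos)
    stop("start tree outside layout")
  set.seed(as.integer(seed))
  u <- if (identical(fp$capture_visit, "uniform"))
    sample.int(fp$n_visits, 1L) else as.integer(fp$capture_visit)
  if (u > fp$n_visits) stop("capture_visit > n_visits")
  path <- .walk(layout, fp, start, n_steps = u - 1L)
  load <- .accumulate_load(layout, path, fp,
                           include_last = isTRUE(fp$capture_pickup %||% TRUE))
  structure(list(grains = load, capture_visit = u,
                 visits = data.frame(row = path[, 1L], pos = path[, 2L],
                                     cultivar = layout$grid[path])),
            class = "pollen_load")
}

.fill_foraging <- function(fp) {
  list(p_row_switch = as.numeric(fp$p_row_switch %||% 0.1),
       n_visits = as.integer(fp$n_visits %||% 30L),
       carryover_retention = as.numeric(fp$carryover_retention %||% 0.7),
       pickup_grains = as.numeric(fp$pickup_grains %||% 1),
       capture_visit = fp$capture_visit %||% "uniform",
       capture_pickup = fp$capture_pickup %||% TRUE)
}

# visit sequence as a (n_steps + 1) x 2 matrix of (row, pos), first row =
# start tree; persistent along-row direction, reflecting at edges
.walk <- function(layout, fp, start, n_steps) {
  nrows <- nrow(layout$grid); npos <- layout$trees_per_row
  path <- matrix(0L, nrow = n_steps + 1L, ncol = 2L)
  r <- as.integer(start[1L]); p <- as.integer(start[2L])
  dir <- sample(c(-1L, 1L), 1L)
  path[1L, ] <- c(r, p)
  if (n_steps > 0L) for (s in seq_len(n_steps)) {
    if (stats::runif(1L) < fp$p_row_switch) {
      dr <- sample(c(-1L, 1L), 1L)
      r2 <- r + dr
      if (r2 < 1L || r2 > nrows) r2 <- r - dr
      r <- r2
    } else {
      p2 <- p + dir
      if (p2 < 1L || p2 > npos) { dir <- -dir; p2 <- p + dir }
      p <- p2
    }
    path[s + 1L, ] <- c(r, p)
  }
  path
}

.accumulate_load <- function(layout, path, fp, include_last = TRUE) {
  rho <- fp$carryover_retention
  load <- numeric(0)
  n <- nrow(path) - if (include_last) 0L else 1L
  if (n >= 1L) for (i in seq_len(n)) {
    load <- load * rho
    cv <- layout$grid[path[i, 1L], path[i, 2L]]
    load[cv] <- (if (cv %in% names(load)) load[[cv]] else 0) +
      fp$pickup_grains
  }
  load[load > 0]
}

#' Simulate allele-presence assays on a pollen load
#'
#' Models the two single-base-extension assays on pooled pollen DNA.  The
#' ALT-dosage fraction at a locus is `sum_c frac(c) * d(c, locus) / 2`,
#' where `d` counts the cultivar's ALT-allele copies (2 homozygous, 1
#' heterozygous, 0 otherwise; a missing genotype contributes 0 and is
#' noted).  The allele is called detected when the fraction reaches
#' `theta_detect`; calls are then flipped false with probability `fn_rate`
#' and true with probability `fp_rate`.  The REF (predominant-allele) assay
#' is computed analogously from REF-allele copies.
#'
#' @param load a [simulate_trip()] pollen load (or any list with a named
#'   `grains` vector).
#' @param pd the panel design.
#' @param ap assay parameters: list with `theta_detect`, `fn_rate`,
#'   `fp_rate`, `seed`.
#' @return A data frame with columns `locus_id`, `alt_detected`,
#'   `ref_detected`.  If cultivars with missing genotypes carried load, the
#'   affected loci are listed in attribute `missing_note`.
#' @export
simulate_assay <- function(load, pd, ap) {
  stopifnot(inherits(pd, "panel_design"))
  grains <- load$grains %||% load
  theta <- as.numeric(ap$theta_detect %||% 0.05)
  fn <- as.numeric(ap$fn_rate %||% 0); fpr <- as.numeric(ap$fp_rate %||% 0)
  if (!is.null(ap$seed)) set.seed(as.integer(ap$seed))
  loci <- names(pd$loci)
  if (length(grains) == 0L || sum(grains) == 0) {
    return(data.frame(locus_id = loci, alt_detected = FALSE,
                      ref_detected = FALSE))
  }
  bad <- setdiff(names(grains), pd$cultivars)
  if (length(bad)) stop("load cultivar not in panel: ",
                        paste(bad, collapse = ", "))
  frac <- grains / sum(grains)
  d_alt <- pd$dosage[, names(frac), drop = FALSE]
  d_ref <- pd$ref_dosage[, names(frac), drop = FALSE]
  note <- loci[rowSums(is.na(d_alt)) > 0 &
                 apply(is.na(d_alt), 1L, function(m) any(frac[m] > 0))]
  d_alt[is.na(d_alt)] <- 0L; d_ref[is.na(d_ref)] <- 0L
  alt_frac <- as.numeric(d_alt %*% frac) / 2
  ref_frac <- as.numeric(d_ref %*% frac) / 2
  alt <- alt_frac >= theta
  ref <- ref_frac >= theta
  flip <- function(x) {
    r <- stats::runif(length(x))
    ifelse(x, r >= fn, r < fpr)
  }
  out <- data.frame(locus_id = loci, alt_detected = flip(alt),
                    ref_detected = flip(ref))
  if (length(note)) attr(out, "missing_note") <- note
  out
}

#' Generate a complete synthetic pollination study
#'
#' Simulates the full field design -- orchard layout, transects into
#' single-cultivar blocks, bees netted during a flower visit at increasing
#' row distances from a cross-pollen source -- and the laboratory assays on
#' each bee's pollen load, with known ground truth.  Each bee's foraging
#' history is a persistent along-row random walk ending at its capture
#' tree; the capture visit itself contributes no pollen pickup (the bee is
#' netted at flower contact).  All randomness derives from one master seed,
#' split deterministically per stage.
#'
#' @param config a study config (see [read_study_config()] and
#'   [orchard_preset()]).  `transects$hosts` lists transect groups as
#'   `list(block=, from=, n_transects=)`: `block` names the target block's cultivar,
#'   `from` is `"start"` or `"end"` (which block edge faces the cross-pollen
#'   source) and `n_transects` the number of transects.
#' @param pd the panel design used for the assays; defaults to the packaged
#'   12-cultivar macadamia panel ([table1_panel()]).
#' @param seed master integer seed.
#' @param outdir if non-`NULL`, the three pipeline CSVs
#'   (`bee_metadata.csv`, `allele_calls.csv`, `ground_truth.csv`) are
#'   written there with provenance headers.
#' @return A list with `metadata` (bee-level design), `calls` (long-format
#'   assay calls), `truth` (true load fractions and true category per bee)
#'   and `layout`.
#' @export
generate_study <- function(config, pd = NULL, seed = 1L, outdir = NULL) {
  if (is.null(pd)) pd <- table1_panel()
  stopifnot(inherits(pd, "panel_design"))
  tr <- config$transects
  fp <- .fill_foraging(config$foraging %||% list())
  fp$capture_pickup <- isTRUE(config$foraging$capture_pickup)
  ap <- config$assay %||% list(theta_detect = 0.05, fn_rate = 0,
                               fp_rate = 0)
  layout <- build_orchard(config$orchard,
                          seed = .stage_seed(seed, 1L))
  rows <- as.integer(tr$rows)
  bees_per_point <- as.integer(tr$bees_per_point)
  if (bees_per_point < 1L) stop("inconsistent config: bees_per_point")
  hosts <- tr$hosts
  n_tr <- sum(vapply(hosts, function(h) as.integer(h$n_transects), integer(1L)))
  cols <- round(seq(1, layout$trees_per_row, length.out = n_tr + 2L))
  cols <- cols[seq(2L, n_tr + 1L)]
  type_letter <- substr(layout$type, 1L, 1L)

  md <- list(); truth <- list(); calls <- list()
  set.seed(.stage_seed(seed, 2L))
  ti <- 0L
  for (h in hosts) {
    blk <- which(layout$blocks$cultivar == as.character(h$block))[1L]
    if (is.na(blk)) stop("inconsistent config: hosts$block ", h$block)
    b_start <- layout$blocks$row_start[blk]
    b_end <- layout$blocks$row_end[blk]
    from_end <- identical(h$from %||% "start", "end")
    for (k in seq_len(as.integer(h$n_transects))) {
      ti <- ti + 1L
      tid <- sprintf("%s%d", type_letter, ti)
      col <- cols[ti]
      for (r in rows) {
        grow <- if (from_end) b_end - r + 1L else b_start + r - 1L
        if (grow < b_start || grow > b_end)
          stop("inconsistent config: transect row ", r,
               " outside block ", h$block)
        # capture trees are block-cultivar trees (off-types not sampled)
        layout$grid[grow, col] <- layout$planted[grow, col]
        host_cv <- layout$planted[grow, col]
        for (b in seq_len(bees_per_point)) {
          bee <- sprintf("%s_r%02d_b%d", tid, r, b)
          u <- if (identical(fp$capture_visit, "uniform"))
            sample.int(fp$n_visits, 1L) else as.integer(fp$capture_visit)
          hist_path <- .walk(layout, fp, c(grow, col), n_steps = u - 1L)
          # walk runs backwards in time from the capture tree; the load is
          # accumulated oldest-first, excluding the capture visit itself
          fwd <- hist_path[rev(seq_len(nrow(hist_path))), , drop = FALSE]
          load <- .accumulate_load(layout, fwd, fp,
                                   include_last = isTRUE(fp$capture_pickup))
          cl <- simulate_assay(list(grains = load), pd = pd, ap = ap)
          md[[bee]] <- data.frame(
            bee_id = bee, transect_id = tid, orchard_type = layout$type,
            row_index = r, distance_m = r * layout$row_spacing_m,
            host_cultivar = host_cv)
          truth[[bee]] <- .truth_row(bee, load, host_cv,
                                     ap$theta_detect %||% 0.05)
          calls[[bee]] <- data.frame(
            bee_id = bee,
            locus_id = rep(cl$locus_id, 2L),
            assay = rep(c("ALT", "REF"), each = nrow(cl)),
            detected = as.integer(c(cl$alt_detected, cl$ref_detected)))
        }
      }
    }
  }
  out <- list(metadata = do.call(rbind, md), calls = do.call(rbind, calls),
              truth = do.call(rbind, truth), layout = layout)
  rownames(out$metadata) <- rownames(out$calls) <- rownames(out$truth) <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    hdr <- provenance_header(seed = seed, config = config)
    .write_csv_with_header(out$metadata,
                           file.path(outdir, "bee_metadata.csv"), hdr)
    .write_csv_with_header(out$calls,
                           file.path(outdir, "allele_calls.csv"), hdr)
    .write_csv_with_header(out$truth,
                           file.path(outdir, "ground_truth.csv"), hdr)
  }
  out
}

.truth_row <- function(bee, load, host_cv, theta) {
  if (length(load) == 0L || sum(load) == 0) {
    return(data.frame(bee_id = bee, true_load = "",
                      detectable_cultivars = "",
                      true_category = "UNDETERMINED"))
  }
  frac <- sort(load / sum(load), decreasing = TRUE)
  det <- names(frac)[frac >= theta]
  self <- host_cv %in% det
  cross <- length(setdiff(det, host_cv)) > 0L
  cat <- if (cross && self) "MIXED" else if (cross) "CROSS_ONLY"
    else if (self) "SELF_ONLY" else "UNDETERMINED"
  data.frame(bee_id = bee,
             true_load = paste(sprintf("%s:%.4f", names(frac), frac),
                               collapse = ";"),
             detectable_cultivars = paste(det, collapse = ";"),
             true_category = cat)
}

# deterministic per-stage seed split from one master seed (kept < 2^31)
.stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage * 104729) %% 2147483629)
}
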
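#' The packaged 12-cultivar macadamia panel
#'
#' Reads the genotype table packaged with `pollenpanel` (12 macadamia
#' cultivars at 18 SNP loci, transcribed as published, including its two
#' missing calls and its out-of-panel "CT" heterozygote entries) and derives
#' the private-allele panel from it.
#'
#' @return A `panel_design` (see [find_private_alleles()]).
#' @export
table1_panel <- function() {
  if (!is.null(.pkg_cache$table1_panel)) return(.pkg_cache$table1_panel)
  path <- system.file("extdata", "table1_genotypes.tsv",
                      package = "pollenpanel")
  pd <- find_private_alleles(read_genotype_table(path))
  .pkg_cache$table1_panel <- pd
  pd
}

.pkg_cache <- new.env(parent = emptyenv())

#' Provenance header lines for output files
#'
#' @param seed master seed (if any).
#' @param config config list or path (hashed with md5).
#' @return Character vector of header lines (written as `#` comments).
#' @export
provenance_header <- function(seed = NULL, config = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("pollenpanel")),
                  error = function(e) "0.0.0")
  lines <- paste0("pollenpanel ", ver)
  if (!is.null(seed)) lines <- c(lines, paste0("seed=", seed))
  if (!is.null(config)) {
    if (is.character(config) && file.exists(config)) {
      h <- unname(tools::md5sum(config))
    } else {
      tf <- tempfile(fileext = ".yaml")
      on.exit(unlink(tf))
      writeLines(yaml::as.yaml(config), tf)
      h <- unname(tools::md5sum(tf))
    }
    lines <- c(lines, paste0("config_md5=", h))
  }
  lines
}

#' Run the analysis stage on a bee-level table
#'
#' Computes per-row carriage proportions, cross-pollen source composition,
#' and the binomial GLMM (pooled across orchards when both are present,
#' plus per-orchard fits), optionally writing `proportions.csv`,
#' `cross_sources.csv` and `glmm_fit.csv`.
#'
#' @param bees bee-level data frame (from [deconvolve_dataset()]).
#' @param outdir optional output directory.
#' @param alpha significance level for the effect report.
#' @param distance_unit passed to [fit_glmm()].
#' @param header_lines provenance lines for output files.
#' @return List with `proportions`, `cross_sources`, `glmm` (pooled fit),
#'   `per_orchard` (list of per-orchard fits) and `report`.
#' @export
run_analysis <- function(bees, outdir = NULL, alpha = 0.05,
                         distance_unit = "rows", header_lines = NULL) {
  if (nrow(bees) == 0L || all(bees$category == "UNDETERMINED"))
    stop("no included bees")
  props <- summarize_proportions(bees)
  srcs <- summarize_cross_sources(bees)
  glmm <- fit_glmm(bees, distance_unit = distance_unit)
  per_orchard <- lapply(
    stats::setNames(nm = sort(unique(as.character(bees$orchard_type)))),
    function(ot) suppressWarnings(
      fit_glmm(bees[bees$orchard_type == ot, , drop = FALSE],
               distance_unit = distance_unit)))
  report <- if (glmm$converged && !glmm$degenerate)
    distance_effect_report(glmm, alpha = alpha) else NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    .write_csv_with_header(props$cells,
                           file.path(outdir, "proportions.csv"),
                           header_lines)
    if (nrow(srcs$groups))
      .write_csv_with_header(srcs$cultivars,
                             file.path(outdir, "cross_sources.csv"),
                             header_lines)
    gl <- glmm$coefficients
    gl$sigma_transect <- glmm$sigma_transect
    gl$converged <- glmm$converged
    .write_csv_with_header(gl, file.path(outdir, "glmm_fit.csv"),
                           header_lines)
  }
  list(proportions = props, cross_sources = srcs, glmm = glmm,
       per_orchard = per_orchard, report = report)
}

#' Run the full pipeline on a config
#'
#' Simulate a study, deconvolve the simulated assay calls against a panel,
#' and analyse the result, writing every stage's files under `outdir`.
#'
#' @param config study config list or YAML path.
#' @param seed master seed.
#' @param outdir output directory (created).
#' @param pd panel design; default [table1_panel()].
#' @param alpha,distance_unit passed to [run_analysis()].
#' @return The [run_analysis()] result list, plus `study` and `bees`.
#' @export
run_pipeline <- function(config, seed = 1L, outdir = NULL,
                         pd = NULL, alpha = 0.05, distance_unit = "rows") {
  if (is.character(config)) config <- read_study_config(config)
  if (is.null(pd)) pd <- table1_panel()
  hdr <- provenance_header(seed = seed, config = config)
  study <- generate_study(config, pd = pd, seed = seed, outdir = outdir)
  bees <- deconvolve_dataset(study$calls, pd, study$metadata)
  if (!is.null(outdir))
    .write_csv_with_header(bees, file.path(outdir, "bees.csv"), hdr)
  res <- run_analysis(bees, outdir = outdir, alpha = alpha,
                      distance_unit = distance_unit, header_lines = hdr)
  c(list(study = study, bees = bees), res)
}

#' Command-line entry point
#'
#' Subcommands: `panel validate --genotypes FILE [--out DIR]`;
#' `simulate --config FILE --seed N --out DIR`;
#' `deconvolve --genotypes FILE --calls FILE --meta FILE --out DIR`;
#' `analyze --bees FILE --out DIR [--alpha A] [--distance rows|meters|min_rows]`;
#' `run-all --config FILE --seed N --out DIR`.
#' A thin `Rscript` wrapper is installed at `inst/cli/pollenpanel`.
#'
#' @param argv character vector of command-line arguments.
#' @return Integer exit status: 0 success, 1 runtime error (e.g. missing
#'   input), 2 usage error.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    cat("usage: pollenpanel <panel validate|simulate|deconvolve|analyze|run-all> [flags]\n")
    2L
  }
  if (length(argv) == 0L) return(usage())
  cmd <- argv[1L]
  flag <- function(name, default = NULL) {
    i <- which(argv == name)
    if (length(i) == 0L) return(default)
    if (i[1L] + 1L > length(argv)) stop("flag ", name, " needs a value")
    argv[i[1L] + 1L]
  }
  need_file <- function(path, what) {
    if (is.null(path)) stop("missing required flag for ", what)
    if (!file.exists(path)) {
      message("input file not found: ", path)
      return(NULL)
    }
    path
  }
  run <- function(expr) {
    tryCatch({ expr; 0L },
             error = function(e) { message("error: ",
                                           conditionMessage(e)); 1L })
  }
  if (cmd == "panel") {
    if (length(argv) < 2L || argv[2L] != "validate") return(usage())
    path <- flag("--genotypes")
    if (is.null(path)) return(usage())
    if (!file.exists(path)) { message("input file not found: ", path)
      return(1L) }
    return(run({
      gm <- read_genotype_table(path)
      pd <- find_private_alleles(gm)
      rep <- validate_panel(pd, gm)
      print(rep)
      out <- flag("--out")
      if (!is.null(out)) {
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        export_panel(pd, file.path(out, "panel.csv"),
                     provenance_header(config = path))
        .write_csv_with_header(rep$cultivars,
                               file.path(out, "panel_validation.csv"),
                               provenance_header(config = path))
      }
    }))
  }
  if (cmd == "simulate" || cmd == "run-all") {
    cfg <- flag("--config")
    if (is.null(cfg)) return(usage())
    if (!file.exists(cfg)) { message("input file not found: ", cfg)
      return(1L) }
    seed <- as.integer(flag("--seed", "1"))
    out <- flag("--out")
    if (is.null(out)) return(usage())
    return(run({
      if (cmd == "simulate")
        generate_study(read_study_config(cfg), seed = seed, outdir = out)
      else
        run_pipeline(cfg, seed = seed, outdir = out,
                     alpha = as.numeric(flag("--alpha", "0.05")),
                     distance_unit = flag("--distance", "rows"))
    }))
  }
  if (cmd == "deconvolve") {
    gpath <- flag("--genotypes")
    cpath <- flag("--calls"); mpath <- flag("--meta")
    out <- flag("--out")
    if (is.null(cpath) || is.null(mpath) || is.null(out)) return(usage())
    for (p in c(gpath, cpath, mpath)) if (!file.exists(p)) {
      message("input file not found: ", p); return(1L) }
    return(run({
      pd <- if (is.null(gpath)) table1_panel() else
        find_private_alleles(read_genotype_table(gpath))
      bees <- deconvolve_dataset(read_calls(cpath), pd,
                                 read_bee_metadata(mpath),
                                 ambiguity = flag("--ambiguity", "any"))
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      .write_csv_with_header(bees, file.path(out, "bees.csv"),
                             provenance_header())
      cat(sprintf("deconvolved %d bees (%d UNDETERMINED)\n", nrow(bees),
                  attr(bees, "n_undetermined")))
    }))
  }
  if (cmd == "analyze") {
    bpath <- flag("--bees")
    if (is.null(bpath)) return(usage())
    if (!file.exists(bpath)) { message("input file not found: ", bpath)
      return(1L) }
    return(run({
      bees <- utils::read.csv(bpath, comment.char = "#")
      res <- run_analysis(bees, outdir = flag("--out"),
                          alpha = as.numeric(flag("--alpha", "0.05")),
                          distance_unit = flag("--distance", "rows"),
                          header_lines = provenance_header(config = bpath))
      print(res$proportions)
      if (!is.null(res$report)) print(res$report)
    }))
  }
  usage()
}
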
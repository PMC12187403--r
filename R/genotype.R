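#' Cultivar-by-locus genotype matrices
#'
#' A `genotype_matrix` holds diploid genotype calls for a set of cultivars at
#' a set of SNP loci.  Genotypes are unordered pairs of nucleotide symbols
#' (`"GT"` and `"TG"` are the same call); missing calls are `NA`.  This is
#' the raw material from which a private-allele diagnostic panel is derived.
#'
#' @param geno character matrix of two-letter genotype calls (or `NA`), with
#'   one row per locus and one column per cultivar; `rownames` are locus ids
#'   and `colnames` cultivar names.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `cultivars` (character), `loci` (character) and `geno` (the call
#'   matrix, row/column order preserved).
#' @examples
#' path <- system.file("extdata", "table1_genotypes.tsv",
#'                     package = "pollenpanel")
#' gm <- read_genotype_table(path)
#' genotype(gm, "741", "27718")
#' @export
genotype_matrix <- function(geno) {
  if (!is.matrix(geno) || !is.character(geno))
    stop("'geno' must be a character matrix")
  loci <- rownames(geno)
  cultivars <- colnames(geno)
  if (is.null(loci) || is.null(cultivars))
    stop("'geno' must have locus rownames and cultivar colnames")
  if (anyDuplicated(loci))
    stop("duplicate locus id: ", loci[duplicated(loci)][1L])
  if (anyDuplicated(cultivars))
    stop("duplicate cultivar name: ", cultivars[duplicated(cultivars)][1L])
  if (length(cultivars) < 2L)
    stop("need at least 2 cultivars")
  for (j in seq_along(cultivars)) {
    for (i in seq_along(loci)) {
      cell <- geno[i, j]
      if (is.na(cell) || identical(cell, "NA")) {
        geno[i, j] <- NA_character_
        next
      }
      if (!grepl("^[ACGT]{2}$", cell))
        stop(sprintf("malformed genotype '%s' at locus %s, cultivar %s",
                     cell, loci[i], cultivars[j]))
      # store unordered pairs in a canonical letter order
      ab <- sort(strsplit(cell, "")[[1L]])
      geno[i, j] <- paste(ab, collapse = "")
    }
  }
  structure(list(cultivars = cultivars, loci = loci, geno = geno),
            class = "genotype_matrix")
}

#' Read a cultivar-by-locus genotype table
#'
#' Reads a CSV or TSV file with one locus per row: first column the locus id,
#' remaining columns one per cultivar, cells holding two-letter genotype
#' calls or `NA`.  The delimiter is auto-detected from the header line.
#'
#' @param path path to the genotype table.
#' @return A [genotype_matrix()].
#' @export
read_genotype_table <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(0), quote = "\"",
                          comment.char = "")
  if (ncol(df) < 3L)
    stop("genotype table needs a locus column plus at least 2 cultivars")
  loci <- trimws(df[[1L]])
  if (anyDuplicated(loci))
    stop("duplicate locus id: ", loci[duplicated(loci)][1L])
  geno <- as.matrix(df[, -1L, drop = FALSE])
  geno <- apply(geno, 2L, trimws)
  if (!is.matrix(geno)) geno <- matrix(geno, nrow = length(loci),
                                       dimnames = list(NULL, names(df)[-1L]))
  rownames(geno) <- loci
  genotype_matrix(geno)
}

#' Look up a genotype call
#'
#' @param gm a [genotype_matrix()].
#' @param cultivar,locus names of the cultivar and locus.
#' @return The two-letter genotype call (letters in canonical order), or
#'   `NA` if missing.
#' @export
genotype <- function(gm, cultivar, locus) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!cultivar %in% gm$cultivars) stop("unknown cultivar: ", cultivar)
  if (!locus %in% gm$loci) stop("unknown locus: ", locus)
  gm$geno[locus, cultivar]
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d loci x %d cultivars (%d missing calls)\n",
              length(x$loci), length(x$cultivars), sum(is.na(x$geno))))
  cat("cultivars:", paste(x$cultivars, collapse = ", "), "\n")
  invisible(x)
}

# dosage of a given base in a genotype call: 0, 1 or 2 copies; NA if missing
.base_dosage <- function(call, base) {
  if (is.na(call)) return(NA_integer_)
  sum(strsplit(call, "")[[1L]] == base)
}
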
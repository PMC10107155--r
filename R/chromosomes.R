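#' Build a chromosome table
#'
#' A chromosome table holds the names and lengths of the chromosomes of the
#' (haploid) genome. The default genome is the 16-chromosome budding-yeast
#' nuclear genome, in which chromosome 1 is the shortest and chromosome 4 the
#' longest; these two anchor the length-dependent segregation bias (see
#' [compute_bias()]).
#'
#' @param name character vector of chromosome identifiers.
#' @param length_bp positive integer vector of chromosome lengths in base
#'   pairs.
#' @return A `data.frame` of class `chrom_table` with columns `name` and
#'   `length_bp`.
#' @seealso [sacCer3_chromosomes()], [mini_chromosomes()],
#'   [read_chromosome_table()]
#' @export
chromosome_table <- function(name, length_bp) {
  if (length(name) != length(length_bp))
    stop("'name' and 'length_bp' must have the same length")
  if (anyDuplicated(name)) stop("chromosome names must be unique")
  length_bp <- as.numeric(length_bp)
  if (any(!is.finite(length_bp)) || any(length_bp <= 0))
    stop("all chromosome lengths must be positive")
  out <- data.frame(name = as.character(name), length_bp = length_bp,
                    stringsAsFactors = FALSE)
  class(out) <- c("chrom_table", "data.frame")
  out
}

#' Read a chromosome table from TSV
#'
#' Expects a tab-separated file with columns `name` and `length_bp`.
#'
#' @param path file path.
#' @return A `chrom_table` (see [chromosome_table()]).
#' @export
read_chromosome_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "length_bp") %in% names(d)))
    stop("chromosome table must have columns 'name' and 'length_bp'")
  chromosome_table(d$name, d$length_bp)
}

#' S288C (sacCer3) nuclear chromosome lengths
#'
#' The 16 nuclear chromosome lengths of the S288C reference assembly, shipped
#' with the package. Chromosomes are named `chr1`..`chr16`; `chr1` is the
#' shortest (230,218 bp) and `chr4` the longest (1,531,933 bp).
#'
#' @return A `chrom_table` with 16 rows.
#' @export
sacCer3_chromosomes <- function() {
  path <- system.file("extdata", "sacCer3_chromosomes.tsv",
                      package = "achiasmate", mustWork = TRUE)
  read_chromosome_table(path)
}

#' Miniature 16-chromosome genome for desk-scale simulation
#'
#' Rescales the sacCer3 chromosome lengths affinely onto
#' `[min_bp, max_bp]` (default 30--230 kb), preserving the length ordering.
#' The segregation-bias formula is affine in length, so bias values computed
#' on the miniature genome equal those on the full genome; only the
#' sequencing-emulation cost shrinks.
#'
#' @param min_bp,max_bp lengths assigned to the shortest and longest
#'   chromosome.
#' @return A `chrom_table` with 16 rows.
#' @export
mini_chromosomes <- function(min_bp = 30000, max_bp = 230000) {
  full <- sacCer3_chromosomes()
  L <- full$length_bp
  scaled <- (L - min(L)) / (max(L) - min(L)) * (max_bp - min_bp) + min_bp
  chromosome_table(full$name, round(scaled))
}

# internal: validate a chromosome table and (by default) the 16-chromosome
# constraint of the yeast model
check_chrom_table <- function(table, n_expected = 16) {
  if (!is.data.frame(table) || !all(c("name", "length_bp") %in% names(table)))
    stop("'table' must be a chromosome table with columns 'name', 'length_bp'")
  if (!is.null(n_expected) && nrow(table) != n_expected)
    stop(sprintf("expected %d chromosomes, got %d", n_expected, nrow(table)))
  if (any(table$length_bp <= 0)) stop("chromosome lengths must be positive")
  invisible(table)
}
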
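#' Chromosome-length-dependent meiosis-I segregation bias
#'
#' Without crossovers, homolog pairs have no chiasmata to direct their
#' meiosis-I disjunction and segregate essentially at random. Chiasma-
#' independent pairing is thought to strengthen with chromosome length, so
#' the per-chromosome segregation probability `x_N` is modelled as affine in
#' chromosome length:
#'
#' \deqn{x_N = \frac{L_N - L_{min}}{L_{max} - L_{min}} (x_{max} - x_{min}) + x_{min}}
#'
#' so that the shortest chromosome gets `x_min` (fixed at 50% for the
#' unbiased model) and the longest gets `x_max`. Under
#' `mode = "disjunction"` (the default) `x_N` is the probability that the two
#' homologs move to opposite poles at MI; under `mode = "co_segregation"`
#' it is the probability that they move to the same pole, i.e. the roles of
#' `x_N` and `1 - x_N` swap. Increasing `x_max` under the default mode drives
#' long chromosomes toward regular disjunction and thus suppresses their
#' disomy formation.
#'
#' @param table a [chromosome_table()]; by default must have 16 chromosomes.
#' @param x_min,x_max probabilities in `[0.5, 1]` assigned to the shortest and
#'   longest chromosome. `x_min = x_max = 0.5` gives unbiased segregation.
#' @param mode `"disjunction"` or `"co_segregation"` (see Details).
#' @param n_expected required number of chromosomes (set to `NULL` or another
#'   integer for reduced test genomes).
#' @return An object of class `segregation_bias`: a list with elements `x`
#'   (named per-chromosome probability vector), `same_pole` (per-chromosome
#'   probability that both homologs enter the same MI daughter), `mode`,
#'   `x_min`, `x_max` and `table`.
#' @examples
#' b <- compute_bias(sacCer3_chromosomes(), 0.5, 0.5)
#' all(b$x == 0.5)
#' @export
compute_bias <- function(table, x_min = 0.5, x_max = 0.5,
                         mode = c("disjunction", "co_segregation"),
                         n_expected = 16) {
  mode <- match.arg(mode)
  check_chrom_table(table, n_expected)
  if (x_min < 0.5 || x_min > 1 || x_max < 0.5 || x_max > 1)
    stop("'x_min' and 'x_max' must lie in [0.5, 1]")
  L <- table$length_bp
  if (max(L) > min(L)) {
    x <- (L - min(L)) / (max(L) - min(L)) * (x_max - x_min) + x_min
  } else {
    x <- rep(x_min, length(L))
  }
  if (any(x < 0 | x > 1)) stop("bias probabilities fall outside [0, 1]")
  names(x) <- table$name
  same_pole <- if (mode == "disjunction") 1 - x else x
  structure(list(x = x, same_pole = same_pole, mode = mode,
                 x_min = x_min, x_max = x_max, table = table),
            class = "segregation_bias")
}

#' @export
print.segregation_bias <- function(x, ...) {
  cat(sprintf("Segregation bias (%s): x_min = %.3f, x_max = %.3f over %d chromosomes\n",
              x$mode, x$x_min, x$x_max, length(x$x)))
  cat(sprintf("  x range: [%.4f, %.4f]; same-pole range: [%.4f, %.4f]\n",
              min(x$x), max(x$x), min(x$same_pole), max(x$same_pole)))
  invisible(x)
}

#' Loss parameters for meiosis II
#'
#' `pa` is the probability that a monosomic chromosome is lost in a spore at
#' meiosis II (the spore then lacks that chromosome and dies); `pb` is the
#' probability that each copy of a disomic pair is lost (turning a
#' heterodisome into a monosome, or -- if both copies fire -- killing the
#' spore). Both apply independently per spore per chromosome, once, on the
#' MII-entry state.
#'
#' @param pa,pb probabilities in `[0, 1]`.
#' @return An object of class `loss_params`.
#' @export
loss_params <- function(pa = 0, pb = 0) {
  if (pa < 0 || pa > 1 || pb < 0 || pb > 1)
    stop("'pa' and 'pb' must be probabilities in [0, 1]")
  structure(list(pa = pa, pb = pb), class = "loss_params")
}

#' @export
print.loss_params <- function(x, ...) {
  cat(sprintf("MII loss parameters: Pa = %.4f (monosome), Pb = %.4f (per disome copy)\n",
              x$pa, x$pb))
  invisible(x)
}
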
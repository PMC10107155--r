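#' Probability that a designated MI daughter is full
#'
#' A designated MI daughter lacks chromosome N exactly when the pair
#' co-segregated into the other daughter, an event of probability `c_N / 2`
#' where `c_N` is the same-pole probability. Independence across chromosomes
#' gives \eqn{\prod_N (1 - c_N/2)}. Unbiased (all `c_N = 1/2`) this is
#' `(3/4)^16` for the yeast genome, about 1.0e-2: roughly 99% of achiasmate
#' meioses produce no viable spore at all.
#'
#' @param bias a [compute_bias()] object.
#' @return Probability (scalar).
#' @export
p_daughter_full <- function(bias) {
  stopifnot(inherits(bias, "segregation_bias"))
  exp(sum(log1p(-bias$same_pole / 2)))
}

#' Per-chromosome pair kernel, conditional on a full MI daughter
#'
#' For each chromosome, conditional on the designated MI daughter carrying a
#' full set, the daughter holds a heterodisome with probability
#' `p_N = (c_N/2) / (1 - c_N/2)` and a monosome (either parent, equally)
#' otherwise. Exact enumeration of the per-spore loss outcomes then yields,
#' per chromosome, the probability that
#' \itemize{
#'   \item both spores retain the chromosome with identical state
#'     (`identical`),
#'   \item both spores retain the chromosome (`both_viable`),
#'   \item a designated single spore retains it (`marginal`).
#' }
#' Products of these kernels over chromosomes give the exact ascus-category
#' fractions (see [category_fractions()]); the kernel is the verification
#' surface for the stochastic simulator.
#'
#' @param bias a [compute_bias()] object.
#' @param loss a [loss_params()] object.
#' @param pb_mode disome-loss convention, `"per_copy"` (each copy lost
#'   independently with probability `pb`) or `"lose_one"` (one uniformly
#'   chosen copy lost with probability `pb`).
#' @return A data.frame with columns `name`, `p_disome`, `identical`,
#'   `both_viable`, `marginal`.
#' @export
pair_kernel <- function(bias, loss, pb_mode = c("per_copy", "lose_one")) {
  pb_mode <- match.arg(pb_mode)
  stopifnot(inherits(bias, "segregation_bias"), inherits(loss, "loss_params"))
  pa <- loss$pa; pb <- loss$pb
  h <- bias$same_pole / 2
  p_dis <- h / (1 - h)

  # one spore's outcome distribution from a disomic MII entry
  if (pb_mode == "per_copy") {
    keep <- (1 - pb)^2; monoA <- pb * (1 - pb); monoB <- monoA; none <- pb^2
  } else {
    keep <- 1 - pb; monoA <- pb / 2; monoB <- pb / 2; none <- 0
  }
  id_dis <- keep^2 + monoA^2 + monoB^2       # same state, both retained
  bv_dis <- (1 - none)^2
  mg_dis <- 1 - none
  id_mono <- (1 - pa)^2
  bv_mono <- (1 - pa)^2
  mg_mono <- 1 - pa

  out <- data.frame(
    name = names(bias$x),
    p_disome = unname(p_dis),
    identical = unname(p_dis * id_dis + (1 - p_dis) * id_mono),
    both_viable = unname(p_dis * bv_dis + (1 - p_dis) * bv_mono),
    marginal = unname(p_dis * mg_dis + (1 - p_dis) * mg_mono),
    stringsAsFactors = FALSE)
  out
}

# product over chromosomes, in log space for numerical robustness when any
# kernel entry is tiny
.log_prod <- function(v) {
  if (any(v == 0)) return(0)
  exp(sum(log(v)))
}

#' Exact ascus-category fractions
#'
#' Closed-form fractions of the four MII ascus categories among tetrads with
#' one full MI daughter (the double-full `multi` case, of order `(1/2)^16`,
#' is ignored; the simulator reports it separately):
#' \deqn{copies = \prod_N identical_N, \quad both = \prod_N bothviable_N,}
#' \deqn{single = 2(\prod_N marginal_N - both), \quad
#'       miidead = 1 - 2\prod_N marginal_N + both.}
#'
#' @inheritParams pair_kernel
#' @return Named numeric vector with elements `copies`, `altered_copies`,
#'   `single`, `mii_dead` (summing to 1), plus the derived `identity_fraction`
#'   (`copies / both`) and `pair_fraction` (`both / (both + single)`).
#' @examples
#' b <- compute_bias(sacCer3_chromosomes())
#' category_fractions(b, loss_params(0.017, 0.013))
#' @export
category_fractions <- function(bias, loss, pb_mode = c("per_copy", "lose_one")) {
  k <- pair_kernel(bias, loss, match.arg(pb_mode))
  copies <- .log_prod(k$identical)
  both <- .log_prod(k$both_viable)
  marg <- .log_prod(k$marginal)
  single <- 2 * (marg - both)
  mii_dead <- 1 - 2 * marg + both
  c(copies = copies, altered_copies = both - copies,
    single = single, mii_dead = mii_dead,
    identity_fraction = if (both > 0) copies / both else NA_real_,
    pair_fraction = if (both + single > 0) both / (both + single) else NA_real_)
}

#' Exact identical-pair fraction
#'
#' The proportion of `copies` among all two-viable-spore asci,
#' `copies / (copies + altered_copies)` -- the quantity matched against the
#' observed dissection counts when fitting `Pb`.
#'
#' @inheritParams pair_kernel
#' @return Probability (scalar).
#' @export
pair_identity_fraction <- function(bias, loss, pb_mode = c("per_copy", "lose_one")) {
  unname(category_fractions(bias, loss, match.arg(pb_mode))["identity_fraction"])
}
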
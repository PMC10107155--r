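# Grid fitting of the MII loss parameters to observed ascus fractions by
# simulation-observation matching, mirroring the two-stage estimation used
# with the dissection data: Pb from the identical-pair fraction at Pa = 0,
# then Pa from the two-viable-spore fraction at the fitted Pb.

run_grid <- function(grid, bias, n, pb_mode, stat, pa = NULL, pb = NULL) {
  vapply(grid, function(g) {
    loss <- if (is.null(pa)) loss_params(pa = g, pb = pb)
            else loss_params(pa = pa, pb = g)
    sim <- simulate_tetrads(n, bias, loss, conditional = TRUE, pb_mode = pb_mode)
    unname(ascus_fractions(sim)[stat])
  }, numeric(1))
}

check_monotone <- function(grid, values, label, window = 5) {
  # smoothed running means must be non-increasing (up to simulation noise)
  if (length(values) < 2 * window) return(invisible(TRUE))
  sm <- stats::filter(values, rep(1 / window, window), sides = 2)
  sm <- sm[!is.na(sm)]
  if (any(diff(sm) > 5e-3))
    warning(sprintf("%s is not monotone non-increasing on the smoothed grid", label))
  invisible(TRUE)
}

#' Fit the disome-copy loss probability Pb
#'
#' Grid search over `Pb` at `Pa = 0`: for each grid value, conditional
#' tetrads are simulated and the proportion of identical pairs (`copies`)
#' among all two-viable-spore asci is recorded; the returned `Pb` is the grid
#' value whose simulated proportion is closest to the target. With 26
#' observed viable pairs of which 20 were identical, the target is
#' 20/26 = 76.9%.
#'
#' @param target_identity_fraction observed `copies / (copies + altered)`
#'   proportion.
#' @param bias a [compute_bias()] object.
#' @param grid `Pb` values to scan (default 0 to 0.30 in steps of 0.001,
#'   i.e. 0.1 percentage points).
#' @param n conditional tetrads per grid point.
#' @param seed optional integer seed.
#' @param pb_mode disome-loss convention.
#' @return List of class `grid_fit`: `estimate`, `grid`, `values` (simulated
#'   fractions), `target`, `statistic`.
#' @export
fit_pb <- function(target_identity_fraction, bias,
                   grid = seq(0, 0.30, by = 0.001), n = 1e5, seed = NULL,
                   pb_mode = c("per_copy", "lose_one")) {
  pb_mode <- match.arg(pb_mode)
  if (length(grid) == 0) stop("'grid' must be non-empty")
  if (any(grid < 0 | grid > 0.30)) stop("'grid' must lie within [0, 0.30]")
  if (!is.null(seed)) set.seed(seed)
  values <- run_grid(grid, bias, n, pb_mode, "identity_fraction", pa = 0)
  check_monotone(grid, values, "identity fraction vs Pb")
  est <- grid[which.min(abs(values - target_identity_fraction))]
  structure(list(estimate = est, grid = grid, values = values,
                 target = target_identity_fraction,
                 statistic = "identity_fraction", n_per_point = n),
            class = "grid_fit")
}

#' Fit the monosome loss probability Pa
#'
#' Grid search over `Pa` at fixed `Pb`: for each grid value, the simulated
#' fraction of two-viable-spore asci among all viable-set asci
#' (`(copies + altered) / (copies + altered + single)`) is matched against
#' the observed rate (71.0% in the dissection data).
#'
#' @param pb fixed disome-copy loss probability (typically the [fit_pb()]
#'   estimate).
#' @param target_pair_fraction observed two-viable-spore fraction among
#'   viable-set asci.
#' @param grid `Pa` values to scan (default 0 to 0.04 in 0.1-point steps).
#' @inheritParams fit_pb
#' @return List of class `grid_fit` (see [fit_pb()]).
#' @export
fit_pa <- function(pb, target_pair_fraction, bias,
                   grid = seq(0, 0.04, by = 0.001), n = 1e5, seed = NULL,
                   pb_mode = c("per_copy", "lose_one")) {
  pb_mode <- match.arg(pb_mode)
  if (length(grid) == 0) stop("'grid' must be non-empty")
  if (any(grid < 0 | grid > 0.04)) stop("'grid' must lie within [0, 0.04]")
  if (!is.null(seed)) set.seed(seed)
  values <- run_grid(grid, bias, n, pb_mode, "pair_fraction", pb = pb)
  check_monotone(grid, values, "pair fraction vs Pa")
  est <- grid[which.min(abs(values - target_pair_fraction))]
  structure(list(estimate = est, grid = grid, values = values,
                 target = target_pair_fraction,
                 statistic = "pair_fraction", n_per_point = n),
            class = "grid_fit")
}

#' @export
print.grid_fit <- function(x, ...) {
  cat(sprintf("Grid fit of %s: estimate = %.4f (target %.4f, %d grid points, %g tetrads/point)\n",
              x$statistic, x$estimate, x$target, length(x$grid), x$n_per_point))
  invisible(x)
}

#' Fit the meiosis-II loss model to observed tetrad data
#'
#' The central estimator of the package. Two observed quantities from tetrad
#' dissection of achiasmate asci identify the two loss probabilities:
#' \enumerate{
#'   \item among two-viable-spore asci, the fraction whose spores carry
#'     identical karyotypes (`identical_pairs / viable_pairs`, default
#'     20/26 = 76.9%) pins down `Pb`, scanned at `Pa = 0`;
#'   \item among all viable-set asci, the fraction with two viable spores
#'     (default 71.0%) then pins down `Pa` at the fitted `Pb`.
#' }
#' Both stages are grid searches with conditional tetrad simulation at each
#' grid point (0.1-percentage-point resolution by default, matching the
#' precision at which the estimates are reported).
#'
#' @param identical_pairs,viable_pairs observed counts of identical and total
#'   two-viable-spore asci (defaults 20 and 26).
#' @param pair_fraction observed two-viable-spore fraction among viable-set
#'   asci (default 0.710).
#' @param bias a [compute_bias()] object; defaults to unbiased segregation on
#'   the sacCer3 genome.
#' @param pb_grid,pa_grid grids for the two stages.
#' @param n conditional tetrads per grid point.
#' @param seed optional integer seed covering both stages.
#' @param pb_mode disome-loss convention.
#' @return An object of class `achiasmate_fit` with components `pa`, `pb`,
#'   the two `grid_fit` stages (`fit_pb`, `fit_pa`), the targets, `bias`,
#'   and the analytic category fractions at the fitted parameters.
#' @examples
#' \donttest{
#' fit <- fit_loss_rates(n = 2e4, seed = 1)
#' coef(fit)
#' }
#' @export
fit_loss_rates <- function(identical_pairs = 20, viable_pairs = 26,
                           pair_fraction = 0.710,
                           bias = compute_bias(sacCer3_chromosomes()),
                           pb_grid = seq(0, 0.30, by = 0.001),
                           pa_grid = seq(0, 0.04, by = 0.001),
                           n = 1e5, seed = NULL,
                           pb_mode = c("per_copy", "lose_one")) {
  pb_mode <- match.arg(pb_mode)
  if (identical_pairs < 0 || viable_pairs <= 0 || identical_pairs > viable_pairs)
    stop("need 0 <= identical_pairs <= viable_pairs, viable_pairs > 0")
  if (pair_fraction < 0 || pair_fraction > 1)
    stop("'pair_fraction' must be a proportion")
  target_id <- identical_pairs / viable_pairs
  if (!is.null(seed)) set.seed(seed)
  stage_pb <- fit_pb(target_id, bias, grid = pb_grid, n = n, pb_mode = pb_mode)
  stage_pa <- fit_pa(stage_pb$estimate, pair_fraction, bias, grid = pa_grid,
                     n = n, pb_mode = pb_mode)
  loss <- loss_params(pa = stage_pa$estimate, pb = stage_pb$estimate)
  structure(list(pa = stage_pa$estimate, pb = stage_pb$estimate,
                 fit_pb = stage_pb, fit_pa = stage_pa,
                 targets = c(identity_fraction = target_id,
                             pair_fraction = pair_fraction),
                 observed = c(identical_pairs = identical_pairs,
                              viable_pairs = viable_pairs),
                 bias = bias, pb_mode = pb_mode, n_per_point = n,
                 seed = seed,
                 fractions = category_fractions(bias, loss, pb_mode),
                 call = match.call()),
            class = "achiasmate_fit")
}

#' @export
print.achiasmate_fit <- function(x, ...) {
  cat("Achiasmate meiosis-II loss model\n")
  cat(sprintf("  Fitted Pb (per disome copy) = %.1f%%  [target identical-pair fraction %.1f%% = %d/%d]\n",
              100 * x$pb, 100 * x$targets["identity_fraction"],
              x$observed["identical_pairs"], x$observed["viable_pairs"]))
  cat(sprintf("  Fitted Pa (monosome)        = %.1f%%  [target two-viable-spore fraction %.1f%%]\n",
              100 * x$pa, 100 * x$targets["pair_fraction"]))
  invisible(x)
}

#' @export
coef.achiasmate_fit <- function(object, ...) c(pa = object$pa, pb = object$pb)

#' @export
summary.achiasmate_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.achiasmate_fit")
}

#' @export
print.summary.achiasmate_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  Grid resolution: Pb %.4f, Pa %.4f; %g conditional tetrads per grid point\n",
              diff(f$fit_pb$grid)[1], diff(f$fit_pa$grid)[1], f$n_per_point))
  cat("  Analytic ascus-category fractions at the fitted parameters:\n")
  fr <- f$fractions[c("copies", "altered_copies", "single", "mii_dead")]
  print(round(fr, 4))
  cat(sprintf("  Analytic identity fraction %.4f, pair fraction %.4f\n",
              f$fractions["identity_fraction"], f$fractions["pair_fraction"]))
  invisible(x)
}

#' Simulate tetrads from a fitted loss model
#'
#' @param object an `achiasmate_fit`.
#' @param nsim number of conditional tetrads.
#' @param seed optional integer seed.
#' @param ... passed to [simulate_tetrads()].
#' @return A `tetrad_sim` object.
#' @export
simulate.achiasmate_fit <- function(object, nsim = 1e5, seed = NULL, ...) {
  simulate_tetrads(nsim, object$bias,
                   loss_params(pa = object$pa, pb = object$pb),
                   seed = seed, conditional = TRUE,
                   pb_mode = object$pb_mode, ...)
}

#' Plot the two grid-search stages of a loss-model fit
#'
#' Left: simulated identical-pair fraction against `Pb`; right: simulated
#' two-viable-spore fraction against `Pa`. Dashed lines mark the targets and
#' the fitted values.
#'
#' @param x an `achiasmate_fit`.
#' @param ... ignored.
#' @export
plot.achiasmate_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (stage in list(x$fit_pb, x$fit_pa)) {
    lab <- if (stage$statistic == "identity_fraction")
      c("Pb (per disome copy)", "identical-pair fraction")
    else c("Pa (monosome)", "two-viable-spore fraction")
    plot(stage$grid, stage$values, type = "l", xlab = lab[1], ylab = lab[2])
    graphics::abline(h = stage$target, lty = 2)
    graphics::abline(v = stage$estimate, lty = 2, col = 2)
  }
  invisible(x)
}
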
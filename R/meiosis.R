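# Chromosome-state codes used throughout: "0" (absent), "A" / "B" (monosome of
# the given parent), "AB" (heterodisome). Integer codes 0:3 in the same order
# are used by the compiled core.

.state_codes <- c("0", "A", "B", "AB")

state_to_int <- function(x) {
  m <- match(x, .state_codes) - 1L
  if (anyNA(m)) stop("invalid chromosome state; allowed: 0, A, B, AB")
  m
}

int_to_state <- function(x) .state_codes[x + 1L]

copy_number <- function(code) c("0" = 0, "A" = 1, "B" = 1, "AB" = 2,
                                "AA" = 2, "BB" = 2)[code]

#' Simulate meiosis-I segregation of one cell
#'
#' Each chromosome's homolog pair either disjoins (one homolog to each MI
#' daughter) or co-segregates (both to the same daughter, chosen with equal
#' probability). The per-chromosome same-pole probability comes from the
#' supplied [compute_bias()] object.
#'
#' @param bias a `segregation_bias` object.
#' @return A 2-row character matrix (daughters x chromosomes) of composition
#'   codes: `"AB"` for both homologs, `"A"`/`"B"` for one, `"0"` for none.
#'   Copies of each chromosome across the two daughters always sum to 2.
#' @export
segregate_mi <- function(bias) {
  stopifnot(inherits(bias, "segregation_bias"))
  K <- length(bias$same_pole)
  d1 <- character(K); d2 <- character(K)
  same <- runif(K) < bias$same_pole
  side <- runif(K) < 0.5
  d1[same & side] <- "AB"; d2[same & side] <- "0"
  d1[same & !side] <- "0"; d2[same & !side] <- "AB"
  d1[!same & side] <- "A"; d2[!same & side] <- "B"
  d1[!same & !side] <- "B"; d2[!same & !side] <- "A"
  out <- rbind(daughter1 = d1, daughter2 = d2)
  colnames(out) <- names(bias$x)
  out
}

#' Simulate meiosis-II division of one MI daughter
#'
#' Each spore inherits one chromatid per homolog present in the daughter
#' (composition `"AB"` gives a heterodisome, `"A"`/`"B"` a monosome, `"0"`
#' nothing). Losses then apply independently per spore per chromosome, once,
#' on that MII-entry state: each copy of a disome is lost with probability
#' `pb` (or, under `pb_mode = "lose_one"`, one uniformly chosen copy is lost
#' with probability `pb`); a monosomic copy is lost with probability `pa`.
#'
#' @param daughter character vector of composition codes for one MI daughter.
#' @param loss a [loss_params()] object.
#' @param pb_mode `"per_copy"` (default) or `"lose_one"` disome-loss
#'   convention.
#' @return A 2-row character matrix (spores x chromosomes) of state codes.
#' @export
segregate_mii <- function(daughter, loss, pb_mode = c("per_copy", "lose_one")) {
  pb_mode <- match.arg(pb_mode)
  stopifnot(inherits(loss, "loss_params"))
  K <- length(daughter)
  spores <- matrix("0", 2, K, dimnames = list(c("spore1", "spore2"), names(daughter)))
  for (s in 1:2) {
    for (c in seq_len(K)) {
      comp <- daughter[c]
      if (comp == "AB") {
        if (pb_mode == "per_copy") {
          lose_a <- runif(1) < loss$pb
          lose_b <- runif(1) < loss$pb
          spores[s, c] <- if (lose_a && lose_b) "0" else if (lose_a) "B" else if (lose_b) "A" else "AB"
        } else {
          spores[s, c] <- if (runif(1) < loss$pb) sample(c("A", "B"), 1) else "AB"
        }
      } else if (comp %in% c("A", "B")) {
        spores[s, c] <- if (runif(1) < loss$pa) "0" else comp
      }
    }
  }
  spores
}

#' Spore viability
#'
#' A spore is viable when it carries at least one copy of every chromosome.
#'
#' @param spore character vector of state codes.
#' @return Logical.
#' @export
spore_viable <- function(spore) all(spore != "0")

#' Classify a tetrad into the ascus categories
#'
#' The four spores of one ascus are classified by the number of viable spores
#' and, for viable pairs, by whether their full per-chromosome states
#' (including parental origin) agree:
#' \describe{
#'   \item{`copies`}{two viable spores with identical karyotypes}
#'   \item{`altered_copies`}{two viable spores differing on >= 1 chromosome}
#'   \item{`single`}{exactly one viable spore}
#'   \item{`mii_dead`}{no viable spore although an MI daughter carried a full
#'     chromosome set (losses at MII killed its spores)}
#'   \item{`mi_dead`}{no viable spore and neither MI daughter was full}
#'   \item{`multi`}{three or more viable spores (both MI daughters full;
#'     reported separately and excluded from the four-category ratios)}
#' }
#'
#' @param spores 4-row (or 2-row, for a single simulated daughter) character
#'   matrix of spore states.
#' @param daughters 2-row character matrix of MI daughter compositions, needed
#'   to separate `mi_dead` from `mii_dead` when no spore survived. If omitted
#'   it is reconstructed from the spores, which is only valid when no loss
#'   occurred.
#' @return A single character string, one of the category names above.
#' @export
classify_tetrad <- function(spores, daughters = NULL) {
  viable <- apply(spores, 1, spore_viable)
  nv <- sum(viable)
  if (nv >= 3) return("multi")
  if (nv == 2) {
    pair <- spores[viable, , drop = FALSE]
    return(if (all(pair[1, ] == pair[2, ])) "copies" else "altered_copies")
  }
  if (nv == 1) return("single")
  if (is.null(daughters)) {
    # lossless reconstruction: daughter composition mirrors its spores
    daughters <- spores[c(1, 3), , drop = FALSE]
  }
  full <- apply(daughters, 1, function(d) all(d != "0"))
  if (any(full)) "mii_dead" else "mi_dead"
}

#' Stochastic tetrad simulation
#'
#' Simulates `n` meioses of an achiasmate diploid: random (optionally
#' length-biased) MI homolog segregation, equational MII with accidental
#' chromosome loss (`Pa`/`Pb`), spore-viability evaluation and ascus
#' classification. With `conditional = TRUE` only tetrads whose designated MI
#' daughter carries a full chromosome set are simulated (drawing that
#' daughter's composition from its exact conditional distribution) -- about a
#' 100-fold saving, since ~99% of unconditional unbiased tetrads are
#' `mi_dead`. The analytic conditioning probability is recorded so
#' unconditional rates can be reconstructed.
#'
#' @param n number of tetrads (conditional tetrads when `conditional`).
#' @param bias a [compute_bias()] object.
#' @param loss a [loss_params()] object.
#' @param seed optional integer seed (applied via [set.seed()]).
#' @param conditional simulate only full-MI-daughter tetrads (default FALSE).
#' @param pb_mode disome-loss convention, `"per_copy"` or `"lose_one"`.
#' @param keep_karyotypes retain up to this many viable-spore karyotypes in
#'   the result (0 = none).
#' @return An object of class `tetrad_sim`: list with `categories` (named
#'   counts), `disomy_hist` (counts of viable spores by number of disomes,
#'   0..K), `chrom_counts` (per-chromosome monoA/monoB/disomyAB tallies over
#'   viable spores), `n_viable_spores`, `n_tetrads`, `p_full` (analytic
#'   probability that a designated MI daughter is full), `karyotypes`
#'   (character matrix, if requested), the parameters and the seed.
#' @examples
#' b <- compute_bias(sacCer3_chromosomes())
#' s <- simulate_tetrads(1e4, b, loss_params(0.017, 0.013),
#'                       seed = 1, conditional = TRUE)
#' s$categories
#' @export
simulate_tetrads <- function(n, bias, loss, seed = NULL, conditional = FALSE,
                             pb_mode = c("per_copy", "lose_one"),
                             keep_karyotypes = 0) {
  pb_mode <- match.arg(pb_mode)
  stopifnot(inherits(bias, "segregation_bias"), inherits(loss, "loss_params"))
  if (n < 1) stop("'n' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  raw <- cpp_simulate_tetrads(as.double(n), unname(bias$same_pole),
                              loss$pa, loss$pb, conditional,
                              pb_mode == "per_copy",
                              as.integer(keep_karyotypes))
  K <- length(bias$x)
  hist <- raw$disomy_hist
  names(hist) <- 0:K
  chrom_counts <- as.data.frame(raw$chrom_counts)
  chrom_counts <- cbind(name = names(bias$x), chrom_counts)
  out <- list(categories = raw$categories, disomy_hist = hist,
              chrom_counts = chrom_counts,
              n_viable_spores = raw$n_viable_spores,
              n_tetrads = raw$n_tetrads,
              p_full = p_daughter_full(bias),
              conditional = conditional, pb_mode = pb_mode,
              bias = bias, loss = loss, seed = seed)
  if (keep_karyotypes > 0 && raw$n_karyotypes > 0) {
    karyo <- matrix(int_to_state(raw$karyotypes[seq_len(raw$n_karyotypes), ,
                                                drop = FALSE]),
                    nrow = raw$n_karyotypes,
                    dimnames = list(NULL, names(bias$x)))
    out$karyotypes <- karyo
  }
  class(out) <- "tetrad_sim"
  out
}

#' @export
print.tetrad_sim <- function(x, ...) {
  cat(sprintf("Tetrad simulation: %s tetrads (%s), Pa = %.4f, Pb = %.4f [%s]\n",
              format(x$n_tetrads, big.mark = ","),
              if (x$conditional) "conditioned on a full MI daughter" else "unconditional",
              x$loss$pa, x$loss$pb, x$pb_mode))
  cat("Ascus categories:\n")
  print(x$categories)
  cat(sprintf("Viable spores: %s; analytic P(full MI daughter) = %.5f\n",
              format(x$n_viable_spores, big.mark = ","), x$p_full))
  invisible(x)
}

#' Ascus-category fractions from a simulation
#'
#' Returns the simulated fraction of each of the four MII categories among
#' full-MI-daughter tetrads (`multi` and `mi_dead` excluded), plus the two
#' derived quantities matched against dissection data: the identical-pair
#' fraction `copies / (copies + altered_copies)` and the two-viable-spore
#' fraction `(copies + altered_copies) / (copies + altered_copies + single)`.
#'
#' @param sim a `tetrad_sim` object.
#' @return Named numeric vector.
#' @export
ascus_fractions <- function(sim) {
  k <- sim$categories
  four <- k[c("copies", "altered_copies", "single", "mii_dead")]
  tot <- sum(four)
  pair <- k[["copies"]] + k[["altered_copies"]]
  c(four / tot,
    identity_fraction = if (pair > 0) k[["copies"]] / pair else NA_real_,
    pair_fraction = pair / (pair + k[["single"]]))
}

#' Distribution of disome counts per viable spore
#'
#' Simulates tetrads and tallies, over all viable spores, how many
#' chromosomes each carries in disomy.
#'
#' @inheritParams simulate_tetrads
#' @return Named numeric vector of counts for 0..K disomes per spore.
#' @export
disomy_distribution <- function(bias, loss, n = 1e5, seed = NULL,
                                conditional = TRUE,
                                pb_mode = c("per_copy", "lose_one")) {
  sim <- simulate_tetrads(n, bias, loss, seed = seed,
                          conditional = conditional,
                          pb_mode = match.arg(pb_mode))
  sim$disomy_hist
}

#' Sample viable spore karyotypes
#'
#' Draws viable spores from the conditional tetrad simulator until `n_spores`
#' have been collected; the workhorse behind synthetic spore cohorts.
#'
#' @param n_spores number of viable spores required.
#' @inheritParams simulate_tetrads
#' @return Character matrix (`n_spores` x K) of state codes with chromosome
#'   names as columns.
#' @export
sample_viable_spores <- function(n_spores, bias, loss, seed = NULL,
                                 pb_mode = c("per_copy", "lose_one")) {
  pb_mode <- match.arg(pb_mode)
  stopifnot(inherits(bias, "segregation_bias"), inherits(loss, "loss_params"))
  if (!is.null(seed)) set.seed(seed)
  raw <- cpp_sample_viable_spores(as.integer(n_spores),
                                  unname(bias$same_pole),
                                  loss$pa, loss$pb, pb_mode == "per_copy")
  matrix(int_to_state(raw), nrow = n_spores,
         dimnames = list(NULL, names(bias$x)))
}
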
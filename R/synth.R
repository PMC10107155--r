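# Synthetic hybrid-diploid sequencing data with known ground truth, emulating
# short-read resequencing of spores from a cross of two diverged parents
# (~0.7% SNP density between the parental genomes).

#' Generate a parental SNP map
#'
#' Samples SNP positions uniformly without replacement along each chromosome
#' at the requested genome-wide density and assigns distinct parental alleles
#' at each site. Positions are 1-based and strictly increasing per
#' chromosome.
#'
#' @param table a [chromosome_table()].
#' @param density per-base probability that a site distinguishes the parents
#'   (default 0.007, i.e. 0.7%).
#' @param seed optional integer seed.
#' @return A data.frame of class `snp_table` with columns `chrom`, `pos`,
#'   `alleleA`, `alleleB`.
#' @export
generate_snp_table <- function(table, density = 0.007, seed = NULL) {
  check_chrom_table(table, n_expected = NULL)
  if (density <= 0) {
    out <- data.frame(chrom = character(), pos = integer(),
                      alleleA = character(), alleleB = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("snp_table", "data.frame")
    return(out)
  }
  if (density >= 1) stop("'density' must be < 1")
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  pieces <- lapply(seq_len(nrow(table)), function(i) {
    L <- table$length_bp[i]
    n <- round(density * L)
    pos <- sort(sample.int(L, n))
    a <- sample(bases, n, replace = TRUE)
    shift <- sample(1:3, n, replace = TRUE)
    b <- bases[((match(a, bases) - 1 + shift) %% 4) + 1]
    data.frame(chrom = table$name[i], pos = pos, alleleA = a, alleleB = b,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("snp_table", "data.frame")
  out
}

#' Ground-truth description of one spore clone
#'
#' @param karyotype named character vector of per-chromosome states. Codes:
#'   `"0"`, `"A"`, `"B"`, `"AB"` (heterodisome) plus `"AA"`/`"BB"` for
#'   duplicated monosomes arising during mitotic passage.
#' @param mosaic named numeric vector (subset of chromosomes) giving, for
#'   disomic chromosomes only, the fraction of cells in the clone that have
#'   lost one copy (partial copy-number reduction).
#' @param mosaic_retained named character vector giving, for each mosaic
#'   chromosome, which parental copy the reduced cells retain (`"A"` or
#'   `"B"`); defaults to `"A"`.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(karyotype, mosaic = numeric(0),
                         mosaic_retained = character(0)) {
  if (is.null(names(karyotype))) stop("'karyotype' must be named by chromosome")
  bad <- setdiff(unique(karyotype), c("0", "A", "B", "AB", "AA", "BB"))
  if (length(bad)) stop("invalid karyotype codes: ", paste(bad, collapse = ", "))
  if (length(mosaic)) {
    if (is.null(names(mosaic))) stop("'mosaic' must be named by chromosome")
    if (any(mosaic < 0 | mosaic > 1)) stop("mosaic fractions must be in [0, 1]")
    not_dis <- names(mosaic)[copy_number(karyotype[names(mosaic)]) != 2]
    if (length(not_dis))
      stop("mosaic fractions are only defined for disomic chromosomes: ",
           paste(not_dis, collapse = ", "))
  }
  ret <- setNames(rep("A", length(mosaic)), names(mosaic))
  if (length(mosaic_retained)) ret[names(mosaic_retained)] <- mosaic_retained
  structure(list(karyotype = karyotype, mosaic = mosaic,
                 mosaic_retained = ret),
            class = "ground_truth")
}

# effective copy number and parent-A allele fraction per chromosome
truth_profile <- function(truth) {
  k <- truth$karyotype
  copies <- setNames(unname(copy_number(k)), names(k))
  nA <- setNames(unname(c("0" = 0, "A" = 1, "B" = 0, "AB" = 1,
                          "AA" = 2, "BB" = 0)[k]), names(k))
  eff <- copies
  fracA <- ifelse(copies > 0, nA / copies, 0.5)
  for (ch in names(truth$mosaic)) {
    phi <- truth$mosaic[[ch]]
    eff[ch] <- copies[ch] - phi
    retA <- as.numeric(truth$mosaic_retained[[ch]] == "A")
    a_eff <- nA[ch] * (1 - phi) + retA * phi
    fracA[ch] <- a_eff / eff[ch]
  }
  data.frame(chrom = names(k), copies = unname(copies),
             effective = unname(eff), fracA = unname(fracA),
             stringsAsFactors = FALSE)
}

#' Simulate a sequencing read profile for one spore clone
#'
#' Emulates short-read resequencing at desk scale: per-bin depth is Poisson
#' with mean `effective_copies * mean_depth_per_copy` (effective copies are
#' `2 - phi` on a mosaic disome and `0` on an absent chromosome, which only
#' receives background depth), and at each SNP the parent-A read count is
#' Binomial over the site depth with success probability
#' `fA (1 - e) + (1 - fA) e`, where `fA` is the fraction of parent-A copies
#' and `e` the substitution error rate. With `noise = FALSE` the expectations
#' themselves are emitted (useful for threshold tests).
#'
#' @param truth a [ground_truth()] object.
#' @param snps a [generate_snp_table()] SNP map.
#' @param table the [chromosome_table()] the SNP map was built on.
#' @param mean_depth_per_copy expected read depth contributed by one
#'   chromosome copy (default 30).
#' @param error_rate per-read substitution error probability (default 0.002).
#' @param bin_size coverage bin width in bp (default 1000; bins are 0-based
#'   half-open and tile each chromosome).
#' @param background_depth expected stray depth on absent chromosomes
#'   (default 0.05).
#' @param noise draw Poisson/Binomial noise (default TRUE).
#' @param seed optional integer seed.
#' @return An object of class `read_profile`: list with `coverage`
#'   (data.frame `chrom`, `start`, `end`, `depth`) and `alleles` (data.frame
#'   `chrom`, `pos`, `countA`, `countB`).
#' @export
simulate_reads <- function(truth, snps, table, mean_depth_per_copy = 30,
                           error_rate = 0.002, bin_size = 1000,
                           background_depth = 0.05, noise = TRUE,
                           seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (mean_depth_per_copy <= 0) stop("'mean_depth_per_copy' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  prof <- truth_profile(truth)
  rownames(prof) <- prof$chrom

  cov_pieces <- lapply(seq_len(nrow(table)), function(i) {
    ch <- table$name[i]; L <- table$length_bp[i]
    starts <- seq(0, L - 1, by = bin_size)
    ends <- pmin(starts + bin_size, L)
    lambda <- max(prof[ch, "effective"] * mean_depth_per_copy, background_depth)
    d <- if (noise) rpois(length(starts), lambda) else rep(lambda, length(starts))
    data.frame(chrom = ch, start = starts, end = ends, depth = d,
               stringsAsFactors = FALSE)
  })
  coverage <- do.call(rbind, cov_pieces)
  rownames(coverage) <- NULL

  eff <- prof[snps$chrom, "effective"]
  fA <- prof[snps$chrom, "fracA"]
  lambda <- pmax(eff * mean_depth_per_copy, background_depth)
  depth <- if (noise) rpois(nrow(snps), lambda) else round(lambda)
  pA <- fA * (1 - error_rate) + (1 - fA) * error_rate
  countA <- if (noise) rbinom(nrow(snps), depth, pA) else round(depth * pA)
  alleles <- data.frame(chrom = snps$chrom, pos = snps$pos,
                        countA = countA, countB = depth - countA,
                        stringsAsFactors = FALSE)
  structure(list(coverage = coverage, alleles = alleles,
                 bin_size = bin_size,
                 mean_depth_per_copy = mean_depth_per_copy),
            class = "read_profile")
}

#' @export
print.read_profile <- function(x, ...) {
  cat(sprintf("Read profile: %d coverage bins (%d bp), %d SNP sites, %d chromosomes\n",
              nrow(x$coverage), x$bin_size, nrow(x$alleles),
              length(unique(x$coverage$chrom))))
  invisible(x)
}

#' Mitotic-passage karyotype evolution
#'
#' Propagates a clone's ground truth through an extended mitotic culture
#' (e.g. 110 generations): each disome is reduced to a monosome with
#' probability `loss_rate` (the retained copy chosen uniformly), and each
#' monosome is duplicated with probability `gain_rate`. Viability is
#' preserved -- no chromosome is ever lost to zero copies.
#'
#' @param truth a [ground_truth()] object (generation 0).
#' @param loss_rate,gain_rate per-chromosome event probabilities in `[0, 1]`.
#' @param seed optional integer seed.
#' @return A new `ground_truth` describing the passaged clone.
#' @export
simulate_passage <- function(truth, loss_rate = 0, gain_rate = 0, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (loss_rate < 0 || loss_rate > 1 || gain_rate < 0 || gain_rate > 1)
    stop("rates must be probabilities in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  k <- truth$karyotype
  for (ch in names(k)) {
    if (copy_number(k[ch]) == 2 && runif(1) < loss_rate) {
      k[ch] <- switch(k[[ch]],
                      AB = sample(c("A", "B"), 1),
                      AA = "A", BB = "B", k[[ch]])
    } else if (copy_number(k[ch]) == 1 && runif(1) < gain_rate) {
      k[ch] <- paste0(k[[ch]], k[[ch]])
    }
  }
  ground_truth(k)
}
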
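# Per-chromosome ploidy and parental-origin calling from SNP allele fractions
# plus binned coverage, and the downstream stability / recombination calls.

#' Caller thresholds
#'
#' Tunable thresholds of the two-pass karyotype caller. `delta` is the
#' allele-fraction tolerance: a chromosome with coverage-weighted mean
#' parent-A fraction above `1 - delta` is provisionally a parent-A monosome,
#' below `delta` a parent-B monosome, anything else biparental. The coverage
#' ratio bands sit midway between integer copy expectations: a monosome
#' baseline ratio near 1, a disome near 2, with `(1.25, 1.75)` flagged as
#' partial copy-number reduction (mosaic loss within the clone).
#'
#' @param delta allele-fraction tolerance (default 0.15).
#' @param mono_band,disomy_band inclusive coverage-ratio bands for one and
#'   two copies.
#' @param none_max coverage ratio below which a chromosome is called absent.
#' @param min_snps minimum informative SNPs per chromosome.
#' @return A list of thresholds.
#' @export
caller_params <- function(delta = 0.15, mono_band = c(0.75, 1.25),
                          disomy_band = c(1.75, 2.25), none_max = 0.25,
                          min_snps = 50) {
  list(delta = delta, mono_band = mono_band, disomy_band = disomy_band,
       none_max = none_max, min_snps = min_snps)
}

#' Call per-chromosome copy state and parental origin
#'
#' Two-pass procedure over one spore clone's [simulate_reads()]-style
#' profile. Pass 1 assigns provisional states from the coverage-weighted
#' mean parent-A allele fraction of each chromosome (monosome A / monosome B
#' / biparental). Pass 2 sets the monosome depth baseline to the median mean
#' depth of the provisional monosomes (falling back, with a warning, to the
#' mode of all chromosome depths when no monosome exists), computes each
#' chromosome's normalized coverage ratio `r`, and resolves biparental
#' chromosomes into heterodisomes (`r` in the disomy band), partial
#' reductions (`r` strictly between the bands; estimated mosaic fraction
#' `2 - r`) or monosomes. Chromosomes with `r` below `none_max` are called
#' absent.
#'
#' @param profile a `read_profile`.
#' @param snps the SNP map the profile was generated against (used for the
#'   informative-SNP check; may be `NULL`).
#' @param params thresholds from [caller_params()].
#' @return A data.frame of class `karyotype_calls` with columns `chrom`,
#'   `state` (`none`, `monoA`, `monoB`, `disomyAB`, `partial_reduction`),
#'   `allele_fraction`, `ratio`, `copy_number`, `n_snps`; the monosome depth
#'   baseline is attached as attribute `baseline`.
#' @export
call_karyotype <- function(profile, snps = NULL, params = caller_params()) {
  stopifnot(inherits(profile, "read_profile"))
  al <- profile$alleles
  cov <- profile$coverage
  chroms <- unique(cov$chrom)

  depth_tot <- tapply(al$countA + al$countB, al$chrom, sum)
  a_tot <- tapply(al$countA, al$chrom, sum)
  n_inf <- tapply(al$countA + al$countB > 0, al$chrom, sum)
  mean_depth <- tapply(cov$depth, cov$chrom, mean)

  fbar <- setNames(rep(NA_real_, length(chroms)), chroms)
  nsnp <- setNames(rep(0L, length(chroms)), chroms)
  ok <- intersect(chroms, names(depth_tot))
  fbar[ok] <- ifelse(depth_tot[ok] > 0, a_tot[ok] / depth_tot[ok], NA_real_)
  nsnp[ok] <- as.integer(n_inf[ok])

  informative <- !is.na(fbar)
  if (any(nsnp[informative] < params$min_snps))
    warning("some chromosomes have fewer than 'min_snps' informative SNPs")

  # pass 1: provisional state from allele fractions alone
  provisional <- ifelse(!informative, "none",
                 ifelse(fbar >= 1 - params$delta, "monoA",
                 ifelse(fbar <= params$delta, "monoB", "biparental")))

  # pass 2: monosome baseline and coverage ratios
  mono <- chroms[provisional %in% c("monoA", "monoB")]
  if (length(mono) > 0) {
    baseline <- median(mean_depth[mono])
    fallback <- FALSE
  } else {
    d <- density(mean_depth[chroms])
    baseline <- d$x[which.max(d$y)]
    fallback <- TRUE
    warning("no provisional monosome available; baseline set to the mode of chromosome depths")
  }
  r <- mean_depth[chroms] / baseline

  state <- character(length(chroms))
  names(state) <- chroms
  for (ch in chroms) {
    if (r[ch] < params$none_max || provisional[ch] == "none") {
      state[ch] <- "none"
    } else if (provisional[ch] %in% c("monoA", "monoB")) {
      state[ch] <- provisional[ch]
    } else if (r[ch] >= params$disomy_band[1]) {
      state[ch] <- "disomyAB"
    } else if (r[ch] > params$mono_band[2]) {
      state[ch] <- "partial_reduction"
    } else {
      state[ch] <- if (fbar[ch] >= 0.5) "monoA" else "monoB"
    }
  }

  out <- data.frame(chrom = chroms, state = unname(state[chroms]),
                    allele_fraction = unname(fbar[chroms]),
                    ratio = unname(r[chroms]),
                    copy_number = unname(r[chroms]),
                    n_snps = unname(nsnp[chroms]),
                    stringsAsFactors = FALSE)
  attr(out, "baseline") <- baseline
  attr(out, "baseline_fallback") <- fallback
  class(out) <- c("karyotype_calls", "data.frame")
  out
}

#' Moving-average smoothing of binned coverage
#'
#' Simple centered moving average per chromosome; edge bins are averaged
#' over the available span, so output length equals input length.
#'
#' @param profile a `read_profile`.
#' @param window window width in bins (default 50).
#' @return The profile with smoothed (numeric) bin depths.
#' @export
smooth_coverage <- function(profile, window = 50) {
  stopifnot(inherits(profile, "read_profile"))
  if (window < 1) stop("'window' must be >= 1")
  half <- floor((window - 1) / 2)
  cov <- profile$coverage
  for (ch in unique(cov$chrom)) {
    idx <- which(cov$chrom == ch)
    d <- cov$depth[idx]
    n <- length(d)
    cs <- cumsum(c(0, d))
    lo <- pmax(seq_len(n) - half, 1)
    hi <- pmin(seq_len(n) + (window - 1 - half), n)
    cov$depth[idx] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  profile$coverage <- cov
  profile
}

#' Classify chromosome stability across mitotic passage
#'
#' Compares a clone's coverage at generation 0 (`g0`) and after extended
#' culture (`g110`). Depths in each profile are first normalized by the
#' median depth of the chromosomes monosomic at g-0 (monosome normalization,
#' which
#' cancels any global depth difference between the two sequencing runs); the
#' per-chromosome g-110/g-0 ratio of these normalized depths is then
#' thresholded: below `min_ratio` (default 0.5) is a copy-number `loss`,
#' above `max_ratio` (default 1.5) a `gain`, otherwise `stable`.
#'
#' @param g0 the generation-0 `read_profile`.
#' @param g0_calls [call_karyotype()] result for `g0` (supplies the monosome
#'   set).
#' @param g110 the passaged clone's `read_profile`.
#' @param min_ratio,max_ratio verdict thresholds (defaults 0.5 and 1.5).
#' @return A data.frame of class `stability_record` with columns `chrom`,
#'   `ratio`, `verdict`.
#' @export
classify_stability <- function(g0, g0_calls, g110,
                               min_ratio = 0.5, max_ratio = 1.5) {
  stopifnot(inherits(g0, "read_profile"), inherits(g110, "read_profile"))
  d0 <- tapply(g0$coverage$depth, g0$coverage$chrom, mean)
  d1 <- tapply(g110$coverage$depth, g110$coverage$chrom, mean)
  chroms <- unique(g0$coverage$chrom)
  if (!setequal(chroms, unique(g110$coverage$chrom)))
    stop("g-0 and g-110 profiles must cover the same chromosomes")
  mono <- g0_calls$chrom[g0_calls$state %in% c("monoA", "monoB")]
  if (length(mono) == 0) stop("no g-0 monosome available for normalization")
  # median over the g-0 monosome set: robust to the occasional baseline
  # chromosome that itself gained a copy during passage
  base0 <- median(d0[mono]); base1 <- median(d1[mono])
  ratio <- (d1[chroms] / base1) / (d0[chroms] / base0)
  verdict <- ifelse(ratio < min_ratio, "loss",
             ifelse(ratio > max_ratio, "gain", "stable"))
  out <- data.frame(chrom = chroms, ratio = unname(ratio),
                    verdict = unname(verdict), stringsAsFactors = FALSE)
  class(out) <- c("stability_record", "data.frame")
  out
}

#' Detect crossovers and gene conversions in a genotype vector
#'
#' Simplified changepoint detector over the parental genotypes of successive
#' SNPs along one (monosomic or phased) chromosome. Isolated single-SNP
#' flips are discarded as noise. An internal run of the opposite parent
#' whose genomic span is at most `max_gc_tract`, flanked on both sides by
#' the same parent, is a gene conversion. Any remaining switch point whose
#' flanking blocks both contain at least `min_block` concordant SNPs is a
#' crossover.
#'
#' @param genotypes character vector of parental calls (`"A"`/`"B"`) at
#'   successive SNPs.
#' @param positions 1-based SNP positions, same length, strictly increasing.
#' @param min_block minimum concordant SNPs on each side of a crossover
#'   (default 20).
#' @param max_gc_tract maximum gene-conversion tract span in bp
#'   (default 10000).
#' @return A list of class `recombination_calls`: `crossovers`,
#'   `gene_conversions` (counts), `co_positions` (midpoints of CO
#'   breakpoints), `gc_tracts` (data.frame `start`, `end`, `n_snps`).
#' @export
detect_recombination <- function(genotypes, positions, min_block = 20,
                                 max_gc_tract = 10000) {
  stopifnot(length(genotypes) == length(positions))
  keep <- genotypes %in% c("A", "B")
  genotypes <- genotypes[keep]; positions <- positions[keep]
  empty <- list(crossovers = 0L, gene_conversions = 0L,
                co_positions = numeric(0),
                gc_tracts = data.frame(start = numeric(0), end = numeric(0),
                                       n_snps = integer(0)))
  class(empty) <- "recombination_calls"
  if (length(genotypes) < 2) return(empty)

  runs <- rle(genotypes)
  # drop isolated single-SNP flips as noise, then re-merge
  while (any(runs$lengths == 1) && length(runs$lengths) > 1) {
    i <- which(runs$lengths == 1)[1]
    gt <- rep(runs$values, runs$lengths)
    drop_idx <- sum(runs$lengths[seq_len(i - 1)]) + 1
    gt <- gt[-drop_idx]; positions <- positions[-drop_idx]
    if (length(gt) < 2) return(empty)
    runs <- rle(gt)
  }
  genotypes <- rep(runs$values, runs$lengths)

  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  span <- positions[ends] - positions[starts]
  nr <- length(runs$lengths)

  gc_idx <- integer(0)
  if (nr >= 3) {
    internal <- 2:(nr - 1)
    gc_idx <- internal[span[internal] <= max_gc_tract]
  }
  gc_tracts <- data.frame(start = positions[starts[gc_idx]],
                          end = positions[ends[gc_idx]],
                          n_snps = runs$lengths[gc_idx])

  # merge GC tracts into their flanks, then call COs at remaining switches
  keep_run <- setdiff(seq_len(nr), gc_idx)
  merged_len <- integer(0); merged_val <- character(0)
  merged_end <- integer(0); merged_start <- integer(0)
  for (i in keep_run) {
    if (length(merged_val) && merged_val[length(merged_val)] == runs$values[i]) {
      j <- length(merged_val)
      merged_len[j] <- merged_len[j] + runs$lengths[i]
      merged_end[j] <- ends[i]
    } else {
      merged_val <- c(merged_val, runs$values[i])
      merged_len <- c(merged_len, runs$lengths[i])
      merged_start <- c(merged_start, starts[i])
      merged_end <- c(merged_end, ends[i])
    }
  }
  co_pos <- numeric(0)
  if (length(merged_val) > 1) {
    for (j in seq_len(length(merged_val) - 1)) {
      if (merged_len[j] >= min_block && merged_len[j + 1] >= min_block) {
        co_pos <- c(co_pos,
                    (positions[merged_end[j]] + positions[merged_start[j + 1]]) / 2)
      }
    }
  }
  out <- list(crossovers = length(co_pos),
              gene_conversions = nrow(gc_tracts),
              co_positions = co_pos, gc_tracts = gc_tracts)
  class(out) <- "recombination_calls"
  out
}

#' @export
print.recombination_calls <- function(x, ...) {
  cat(sprintf("Recombination calls: %d crossover(s), %d gene conversion(s)\n",
              x$crossovers, x$gene_conversions))
  invisible(x)
}

#' Detect recombination across all callable chromosomes of a profile
#'
#' Runs [call_genotypes()] + [detect_recombination()] over every chromosome
#' called monosomic in `calls`. Heterodisomic (unphased) chromosomes are
#' skipped with a warning -- both parental haplotypes are present, so
#' genotype switches along the chromosome carry no recombination signal.
#'
#' @param profile a `read_profile`.
#' @param calls a [call_karyotype()] result for the same profile.
#' @inheritParams detect_recombination
#' @param min_depth minimum SNP depth for a genotype call.
#' @return A data.frame with one row per analysed chromosome: `chrom`,
#'   `crossovers`, `gene_conversions`.
#' @export
detect_recombination_profile <- function(profile, calls, min_block = 20,
                                         max_gc_tract = 10000, min_depth = 3) {
  skip <- calls$chrom[calls$state %in% c("disomyAB", "partial_reduction")]
  if (length(skip))
    warning("skipping unphased disomic chromosome(s): ",
            paste(skip, collapse = ", "))
  use <- calls$chrom[calls$state %in% c("monoA", "monoB")]
  if (length(use) == 0)
    return(data.frame(chrom = character(), crossovers = integer(),
                      gene_conversions = integer(), stringsAsFactors = FALSE))
  rows <- lapply(use, function(ch) {
    g <- call_genotypes(profile, ch, min_depth = min_depth)
    ok <- !is.na(g$genotypes)
    rc <- detect_recombination(g$genotypes[ok], g$positions[ok],
                               min_block = min_block,
                               max_gc_tract = max_gc_tract)
    data.frame(chrom = ch, crossovers = rc$crossovers,
               gene_conversions = rc$gene_conversions,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Call parental genotypes at SNPs from allele depths
#'
#' Majority vote per SNP: `"A"` when more reads support the parent-A allele,
#' `"B"` when fewer, `NA` on ties or depth below `min_depth`. Intended for
#' monosomic (or otherwise phased) chromosomes ahead of
#' [detect_recombination()]; heterodisomic chromosomes are unphased and
#' should be skipped.
#'
#' @param profile a `read_profile`.
#' @param chrom chromosome name.
#' @param min_depth minimum SNP depth (default 3).
#' @return A list with `genotypes` and `positions`.
#' @export
call_genotypes <- function(profile, chrom, min_depth = 3) {
  al <- profile$alleles[profile$alleles$chrom == chrom, ]
  depth <- al$countA + al$countB
  g <- ifelse(al$countA > al$countB, "A",
       ifelse(al$countB > al$countA, "B", NA))
  g[depth < min_depth] <- NA
  list(genotypes = g, positions = al$pos)
}
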
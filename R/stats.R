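# Cohort-level aneuploidy statistics: per-chromosome disomy tallies, length
# normalization, band-subset correlation, dosage-sensitive-gene impact and
# parental-origin bias.

# normalize a cohort to a spores x chromosomes character matrix of codes
as_karyotype_matrix <- function(cohort) {
  if (is.matrix(cohort)) return(cohort)
  if (is.data.frame(cohort) && all(c("sample", "chrom", "state") %in% names(cohort))) {
    code <- c(none = "0", monoA = "A", monoB = "B", disomyAB = "AB",
              partial_reduction = "AB")[cohort$state]
    samples <- unique(cohort$sample)
    chroms <- unique(cohort$chrom)
    m <- matrix("0", length(samples), length(chroms),
                dimnames = list(samples, chroms))
    m[cbind(match(cohort$sample, samples), match(cohort$chrom, chroms))] <- code
    return(m)
  }
  stop("'cohort' must be a karyotype matrix or a calls data.frame with sample/chrom/state")
}

#' Tally aneuploidies across a spore cohort
#'
#' Counts, per chromosome, the spores carrying that chromosome in disomy.
#' Partial copy-number reductions count as disomies at formation (the clone
#' started with two copies and lost one in part of the culture). A per-spore
#' histogram of disomy counts is returned alongside.
#'
#' @param cohort either a spores x chromosomes character matrix of state
#'   codes (`"0"`, `"A"`, `"B"`, `"AB"`, `"AA"`, `"BB"`) as produced by
#'   [sample_viable_spores()], or a long-format data.frame of
#'   [call_karyotype()] results with columns `sample`, `chrom`, `state`.
#' @param table a [chromosome_table()] for the counts/Mbp normalization.
#' @return An object of class `aneuploidy_counts`: data.frame with columns
#'   `chrom`, `length_bp`, `count`, `counts_per_mbp`, with the per-spore
#'   disomy histogram as attribute `per_spore`.
#' @export
count_aneuploidies <- function(cohort, table) {
  m <- as_karyotype_matrix(cohort)
  if (nrow(m) == 0) stop("empty cohort")
  check_chrom_table(table, n_expected = NULL)
  if (!all(colnames(m) %in% table$name))
    stop("cohort chromosomes missing from the chromosome table")
  dis <- matrix(copy_number(m) == 2, nrow(m), ncol(m))
  count <- setNames(colSums(dis), colnames(m))
  len <- setNames(table$length_bp, table$name)[colnames(m)]
  out <- data.frame(chrom = colnames(m), length_bp = unname(len),
                    count = unname(count),
                    counts_per_mbp = unname(count * 1e6 / len),
                    stringsAsFactors = FALSE)
  per_spore <- tabulate(rowSums(dis) + 1, nbins = ncol(m) + 1)
  names(per_spore) <- 0:ncol(m)
  attr(out, "per_spore") <- per_spore
  class(out) <- c("aneuploidy_counts", "data.frame")
  out
}

#' Select chromosomes within a counts/Mbp band
#'
#' Returns the chromosomes whose length-normalized aneuploidy count lies in
#' `[low, high]`. With the defaults (10 and 25 counts/Mbp) this reproduces
#' the band used to exclude the extreme chromosomes before the
#' length-correlation analysis.
#'
#' @param counts an [count_aneuploidies()] result.
#' @param low,high inclusive band limits in counts per Mbp.
#' @return Character vector of retained chromosome names.
#' @export
band_subset <- function(counts, low = 10, high = 25) {
  if (low >= high) stop("'low' must be < 'high'")
  counts$chrom[counts$counts_per_mbp >= low & counts$counts_per_mbp <= high]
}

#' Correlation of aneuploidy counts with chromosome length
#'
#' Pearson correlation (and least-squares line) of raw disomy counts against
#' chromosome length over a chromosome subset, with the full-set correlation
#' reported alongside. On the dissection data the band subset gives a strong
#' positive correlation while the full set is weakly negative -- the extreme
#' chromosomes (very short ones and the heavily selected-against long
#' chromosome 4) break the length trend.
#'
#' @param counts an [count_aneuploidies()] result.
#' @param subset chromosome names to include (default: all).
#' @return A list with `r_subset`, `r_all`, `fit` (the subset [lm()]), and
#'   `subset`.
#' @export
length_correlation <- function(counts, subset = NULL) {
  if (is.null(subset)) subset <- counts$chrom
  sel <- counts[counts$chrom %in% subset, ]
  if (nrow(sel) < 3) stop("need at least 3 chromosomes in the subset")
  if (stats::sd(sel$count) == 0 || stats::sd(sel$length_bp) == 0)
    stop("degenerate variance in the subset")
  fit <- lm(count ~ length_bp, data = sel)
  list(r_subset = cor(sel$count, sel$length_bp),
       r_all = if (stats::sd(counts$count) > 0)
         cor(counts$count, counts$length_bp) else NA_real_,
       fit = fit, subset = sel$chrom)
}

#' Read a dosage-sensitive-gene table
#'
#' Tab-separated with columns `gene`, `chrom`, `copy_limit` (the maximum
#' tolerated extra copy number; 1 means even a single extra copy is barely
#' tolerated).
#'
#' @param path file path; defaults to the synthetic fixture shipped with the
#'   package (the real experimentally derived table is external data and is
#'   not redistributed here).
#' @return A data.frame of class `dsg_table`.
#' @export
read_dsg_table <- function(path = system.file("extdata", "synthetic_dsg.tsv",
                                              package = "achiasmate",
                                              mustWork = TRUE)) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "chrom", "copy_limit") %in% names(d)))
    stop("DSG table must have columns 'gene', 'chrom', 'copy_limit'")
  if (any(d$copy_limit < 1)) stop("copy limits must be >= 1")
  class(d) <- c("dsg_table", "data.frame")
  d
}

#' Total dosage-sensitive-gene impact per chromosome
#'
#' A gene whose copy-number limit is `L` tolerates at most `L` extra copies;
#' its dosage burden when the whole chromosome is duplicated is scored as
#' `1 / L`, and the total DSG impact of a chromosome is the sum of these
#' inverses over its genes. Chromosomes without DSGs score 0.
#'
#' @param dsgs a [read_dsg_table()]-style data.frame.
#' @param table a [chromosome_table()].
#' @return Named numeric vector of impacts, one entry per chromosome.
#' @export
dsg_impact <- function(dsgs, table) {
  check_chrom_table(table, n_expected = NULL)
  if (any(dsgs$copy_limit < 1)) stop("copy limits must be >= 1")
  imp <- setNames(rep(0, nrow(table)), table$name)
  if (nrow(dsgs) > 0) {
    s <- tapply(1 / dsgs$copy_limit, dsgs$chrom, sum)
    imp[names(s)] <- s
  }
  imp
}

#' Association of aneuploidy counts with log DSG impact
#'
#' Pearson correlation between per-chromosome aneuploidy counts and the
#' natural log of the total DSG impact (`transform = "ln_impact"`, default)
#' or of both variables (`"ln_both"`). Chromosomes with zero impact (or, for
#' `"ln_both"`, zero counts) are excluded with a warning. On the dissection
#' data this association is negative: chromosomes dense in dosage-sensitive
#' genes survive disomy less often.
#'
#' @param counts an [count_aneuploidies()] result.
#' @param impact a [dsg_impact()] vector.
#' @param transform `"ln_impact"` or `"ln_both"`.
#' @return A list with `r`, `n_used`, `excluded`.
#' @export
log_association <- function(counts, impact,
                            transform = c("ln_impact", "ln_both")) {
  transform <- match.arg(transform)
  imp <- impact[counts$chrom]
  use <- imp > 0
  if (transform == "ln_both") use <- use & counts$count > 0
  if (any(!use))
    warning("excluding chromosomes with zero impact",
            if (transform == "ln_both") " or zero counts" else "")
  if (sum(use) < 3) stop("fewer than 3 usable chromosomes")
  x <- log(imp[use])
  y <- if (transform == "ln_both") log(counts$count[use]) else counts$count[use]
  if (stats::sd(x) == 0) stop("impact is constant; correlation undefined")
  list(r = cor(y, x), n_used = sum(use),
       excluded = counts$chrom[!use])
}

#' Parental-origin bias across a spore cohort
#'
#' Counts, per chromosome and overall, how many retained homologs derive
#' from parent A versus parent B: a monosome contributes one homolog of its
#' parent, a heterodisome one of each. Binomial 95% confidence intervals are
#' attached (Clopper-Pearson, via [binom.test()]).
#'
#' @param cohort karyotype matrix or calls data.frame (see
#'   [count_aneuploidies()]).
#' @return A list with `per_chromosome` (data.frame `chrom`, `nA`, `nB`,
#'   `fracA`, `ci_lo`, `ci_hi`) and `overall` (same fields, one row).
#' @export
parental_bias <- function(cohort) {
  m <- as_karyotype_matrix(cohort)
  if (nrow(m) == 0) stop("empty cohort")
  nA_code <- c("0" = 0, "A" = 1, "B" = 0, "AB" = 1, "AA" = 2, "BB" = 0)
  nB_code <- c("0" = 0, "A" = 0, "B" = 1, "AB" = 1, "AA" = 0, "BB" = 2)
  nA <- colSums(matrix(nA_code[m], nrow(m), ncol(m)))
  nB <- colSums(matrix(nB_code[m], nrow(m), ncol(m)))
  ci <- function(a, b) {
    if (a + b == 0) return(c(NA_real_, NA_real_))
    as.numeric(binom.test(a, a + b)$conf.int)
  }
  cis <- t(mapply(ci, nA, nB))
  per <- data.frame(chrom = colnames(m), nA = unname(nA), nB = unname(nB),
                    fracA = unname(nA / (nA + nB)),
                    ci_lo = cis[, 1], ci_hi = cis[, 2],
                    stringsAsFactors = FALSE)
  tot <- ci(sum(nA), sum(nB))
  overall <- data.frame(chrom = "all", nA = sum(nA), nB = sum(nB),
                        fracA = sum(nA) / (sum(nA) + sum(nB)),
                        ci_lo = tot[1], ci_hi = tot[2],
                        stringsAsFactors = FALSE)
  list(per_chromosome = per, overall = overall)
}
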
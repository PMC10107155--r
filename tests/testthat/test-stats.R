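test_that("aneuploidy tallies count disomies per chromosome and per spore", {
  tb <- sacCer3_chromosomes()
  chroms <- tb$name
  euploid <- setNames(rep("A", 16), chroms)
  sp2 <- euploid; sp2[c("chr3", "chr5", "chr7", "chr10")] <- "AB"
  cohort <- fixed_cohort(chroms, list(euploid, sp2))
  ac <- count_aneuploidies(cohort, tb)
  expect_equal(sum(ac$count), 4)
  expect_equal(ac$count[ac$chrom %in% c("chr3", "chr5", "chr7", "chr10")],
               rep(1, 4))
  expect_equal(unname(attr(ac, "per_spore")[c("0", "4")]), c(1, 1))
  expect_equal(ac$counts_per_mbp, ac$count * 1e6 / ac$length_bp)
  euploid_only <- fixed_cohort(chroms, list(euploid, euploid))
  expect_true(all(count_aneuploidies(euploid_only, tb)$count == 0))
  expect_error(count_aneuploidies(euploid_only[0, , drop = FALSE], tb), "empty")
})

test_that("partial reductions count as aneuploid at formation", {
  tb <- sacCer3_chromosomes()
  calls <- data.frame(sample = "s1", chrom = tb$name,
                      state = c("partial_reduction", rep("monoA", 15)),
                      stringsAsFactors = FALSE)
  ac <- count_aneuploidies(calls, tb)
  expect_equal(ac$count[ac$chrom == "chr1"], 1)
  expect_equal(sum(ac$count), 1)
})

test_that("the counts/Mbp band recovers the mid-density chromosome subset", {
  tb <- sacCer3_chromosomes()
  # per-chromosome disomy densities shaped like the dissection profile:
  # four high outliers (> 25 / Mbp), three low (< 10 / Mbp), nine mid-band
  dens <- setNames(rep(15, 16), tb$name)
  dens[c("chr1", "chr3", "chr8", "chr11")] <- 30
  dens[c("chr4", "chr15", "chr16")] <- 5
  count <- round(dens * tb$length_bp / 1e6)
  ac <- data.frame(chrom = tb$name, length_bp = tb$length_bp,
                   count = unname(count),
                   counts_per_mbp = unname(count) * 1e6 / tb$length_bp,
                   stringsAsFactors = FALSE)
  class(ac) <- c("aneuploidy_counts", "data.frame")
  band <- band_subset(ac, 10, 25)
  expect_setequal(band, paste0("chr", c(2, 5, 6, 7, 9, 10, 12, 13, 14)))
  excluded <- setdiff(ac$chrom, band)
  expect_length(excluded, 7)
  expect_setequal(union(band, excluded), tb$name)
  expect_setequal(band_subset(ac, 0, Inf), tb$name)
  expect_error(band_subset(ac, 10, 10), "<")
})

test_that("length correlation is exact on proportional counts and small on permuted ones", {
  tb <- sacCer3_chromosomes()
  ac <- data.frame(chrom = tb$name, length_bp = tb$length_bp,
                   count = tb$length_bp / 1e5,
                   counts_per_mbp = 10, stringsAsFactors = FALSE)
  class(ac) <- c("aneuploidy_counts", "data.frame")
  lc <- length_correlation(ac)
  expect_equal(lc$r_subset, 1)
  expect_equal(unname(coef(lc$fit)["length_bp"]), 1e-5, tolerance = 1e-10)

  set.seed(41)
  acp <- ac
  acp$count <- sample(ac$count)
  r_obs <- length_correlation(acp)$r_subset
  null_r <- replicate(500, {
    a2 <- acp; a2$count <- sample(acp$count)
    length_correlation(a2)$r_subset
  })
  expect_gte(mean(abs(null_r) >= abs(r_obs)), 0.01) # unremarkable under the null
  expect_error(length_correlation(ac, subset = c("chr1", "chr2")), "at least 3")
})

test_that("correlations agree with the explicit Pearson formula", {
  tb <- sacCer3_chromosomes()
  set.seed(42)
  ac <- data.frame(chrom = tb$name, length_bp = tb$length_bp,
                   count = rpois(16, 10), counts_per_mbp = 1,
                   stringsAsFactors = FALSE)
  class(ac) <- c("aneuploidy_counts", "data.frame")
  lc <- length_correlation(ac)
  x <- ac$length_bp; y <- ac$count
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(lc$r_subset, manual, tolerance = 1e-12)
})

test_that("DSG impact sums inverse copy limits per chromosome", {
  tb <- sacCer3_chromosomes()
  dsg <- data.frame(gene = c("g1", "g2", "g3"),
                    chrom = c("chr2", "chr2", "chr5"),
                    copy_limit = c(2, 10, 1), stringsAsFactors = FALSE)
  imp <- dsg_impact(dsg, tb)
  expect_equal(unname(imp["chr2"]), 0.6)
  expect_equal(unname(imp["chr5"]), 1.0) # a limit-1 gene is the strongest contributor
  expect_equal(unname(imp["chr3"]), 0)
  expect_equal(sum(dsg_impact(dsg[0, ], tb)), 0)
  expect_error(dsg_impact(transform(dsg, copy_limit = c(2, 0.5, 1)), tb), ">= 1")
  # additive under table concatenation
  imp2 <- dsg_impact(rbind(dsg, dsg), tb)
  expect_equal(unname(imp2), unname(2 * imp))
  # shipped synthetic fixture loads and scores
  fix <- read_dsg_table()
  expect_true(all(fix$copy_limit >= 1))
  expect_true(all(dsg_impact(fix, tb) >= 0))
})

test_that("log association has the right sign, exact limits and guards", {
  tb <- sacCer3_chromosomes()
  imp <- setNames(seq(0.1, 1.6, by = 0.1), tb$name)
  ac <- data.frame(chrom = tb$name, length_bp = tb$length_bp,
                   count = -log(imp), counts_per_mbp = 1,
                   stringsAsFactors = FALSE)
  class(ac) <- c("aneuploidy_counts", "data.frame")
  la <- log_association(ac, imp)
  expect_equal(la$r, -1, tolerance = 1e-12)
  imp0 <- imp; imp0[1:2] <- 0
  expect_warning(la0 <- log_association(ac, imp0), "zero impact")
  expect_equal(la0$n_used, 14)
  expect_error(suppressWarnings(log_association(ac, setNames(rep(1, 16), tb$name))),
               "constant")
})

test_that("survival penalty by DSG impact induces a negative log association", {
  tb <- sacCer3_chromosomes()
  b <- yeast_bias()
  imp <- setNames(exp(seq(log(0.05), log(3), length.out = 16)), tb$name)
  set.seed(43)
  spores <- sample_viable_spores(400, b, loss_params(0, 0), seed = 43)
  # a disome survives in proportion to exp(-k * impact) of its chromosome
  k <- 1.2
  for (ch in colnames(spores)) {
    dis <- spores[, ch] == "AB"
    drop <- dis & runif(nrow(spores)) > exp(-k * imp[ch])
    spores[drop, ch] <- sample(c("A", "B"), sum(drop), replace = TRUE)
  }
  ac <- count_aneuploidies(spores, tb)
  la <- log_association(ac, imp)
  expect_lt(la$r, -0.5)
})

test_that("parental bias counts homologs symmetrically and flags planted bias", {
  chroms <- sacCer3_chromosomes()$name
  allA <- fixed_cohort(chroms, list(setNames(rep("A", 16), chroms),
                                    setNames(rep("A", 16), chroms)))
  pb <- parental_bias(allA)
  expect_equal(pb$overall$fracA, 1.0)
  # unbiased simulated cohort: overall fraction near 0.5, inside its CI
  spores <- sample_viable_spores(200, yeast_bias(), loss_params(0.017, 0.013),
                                 seed = 44)
  pb2 <- parental_bias(spores)
  expect_true(pb2$overall$ci_lo <= 0.5 && 0.5 <= pb2$overall$ci_hi)
  # disomies contribute one homolog of each parent
  one_dis <- setNames(rep("B", 16), chroms); one_dis["chr1"] <- "AB"
  pb3 <- parental_bias(fixed_cohort(chroms, list(one_dis)))
  expect_equal(pb3$per_chromosome$nA[pb3$per_chromosome$chrom == "chr1"], 1)
  expect_equal(pb3$overall$nA, 1)
  expect_equal(pb3$overall$nB, 16)
  # planted survival penalty against parent A detected outside the CI
  set.seed(45)
  spores_pen <- spores
  for (ch in colnames(spores_pen)) {
    hit <- spores_pen[, ch] == "A" & runif(nrow(spores_pen)) < 0.5
    spores_pen[hit, ch] <- "B"
  }
  pb4 <- parental_bias(spores_pen)
  expect_lt(pb4$overall$ci_hi, 0.5)
})
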
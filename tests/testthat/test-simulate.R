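test_that("simulation is reproducible given a seed", {
  b <- yeast_bias()
  l <- loss_params(0.017, 0.013)
  s1 <- simulate_tetrads(5000, b, l, seed = 42, conditional = TRUE,
                         keep_karyotypes = 50)
  s2 <- simulate_tetrads(5000, b, l, seed = 42, conditional = TRUE,
                         keep_karyotypes = 50)
  expect_identical(s1$categories, s2$categories)
  expect_identical(s1$disomy_hist, s2$disomy_hist)
  expect_identical(s1$karyotypes, s2$karyotypes)
  s3 <- simulate_tetrads(5000, b, l, seed = 43, conditional = TRUE)
  expect_false(identical(s1$categories, s3$categories))
})

test_that("summary invariants hold", {
  b <- yeast_bias(x_max = 0.8)
  s <- simulate_tetrads(20000, b, loss_params(0.02, 0.02), seed = 7,
                        conditional = TRUE)
  expect_equal(sum(s$categories), s$n_tetrads)
  expect_equal(sum(s$disomy_hist), s$n_viable_spores)
  expect_equal(sum(s$chrom_counts$disomyAB),
               sum(as.integer(names(s$disomy_hist)) * s$disomy_hist))
  u <- simulate_tetrads(20000, b, loss_params(0.02, 0.02), seed = 8)
  expect_equal(sum(u$categories), u$n_tetrads)
})

test_that("viable-spore karyotypes contain no absent chromosome and only heterodisomes", {
  k <- sample_viable_spores(300, yeast_bias(), loss_params(0.017, 0.013), seed = 5)
  expect_equal(dim(k), c(300, 16))
  expect_true(all(k %in% c("A", "B", "AB")))
})

test_that("unconditional viability matches the closed form", {
  b <- yeast_bias()
  n <- 5e5
  u <- simulate_tetrads(n, b, loss_params(0, 0), seed = 11)
  p <- (3 / 4)^16 # per-spore viability, pa = pb = 0
  expect_lt(abs(u$n_viable_spores / (4 * n) - p), three_se(p, 4 * n))
  # all viable-set asci are identical pairs without a loss channel
  expect_equal(unname(u$categories["altered_copies"]), 0)
  expect_equal(unname(u$categories["single"]), 0)
  expect_equal(unname(u$categories["mii_dead"]), 0)
})

test_that("lossless conditional disomy counts are Binomial(16, 1/3)", {
  b <- yeast_bias()
  n <- 2e5
  h <- disomy_distribution(b, loss_params(0, 0), n = n, seed = 13)
  n_spores <- sum(h)
  expect_equal(n_spores, 2 * n) # every spore of a full daughter is viable
  pk <- stats::dbinom(0:16, 16, 1 / 3)
  # 3 SE per bin plus an allowance for testing ~14 bins jointly
  for (i in which(pk > 1e-4)) {
    expect_lt(abs(h[i] / n_spores - pk[i]), three_se(pk[i], n_spores) * 1.2)
  }
})

test_that("simulator category frequencies match the oracle across parameter settings", {
  n <- 2e5
  settings <- list(
    list(pa = 0, pb = 0.013, x_max = 0.5, mode = "disjunction"),
    list(pa = 0.017, pb = 0.013, x_max = 0.5, mode = "disjunction"),
    list(pa = 0.017, pb = 0.013, x_max = 0.8, mode = "disjunction"),
    list(pa = 0.03, pb = 0.05, x_max = 1.0, mode = "disjunction"),
    list(pa = 0.01, pb = 0.02, x_max = 0.7, mode = "co_segregation"))
  for (i in seq_along(settings)) {
    st <- settings[[i]]
    b <- yeast_bias(x_max = st$x_max, mode = st$mode)
    l <- loss_params(st$pa, st$pb)
    s <- simulate_tetrads(n, b, l, seed = 100 + i, conditional = TRUE)
    f <- category_fractions(b, l)
    for (catg in c("copies", "altered_copies", "single", "mii_dead")) {
      p <- unname(f[catg])
      # 3 SE per comparison plus an allowance for the 20-comparison family
      expect_lt(abs(s$categories[[catg]] / n - p), three_se(p, n) * 1.2 + 1e-9)
    }
  }
})

test_that("per-chromosome disomy rates among viable spores match the kernel ratios", {
  b <- yeast_bias(x_max = 0.8)
  l <- loss_params(0.017, 0.013)
  n <- 2e5
  s <- simulate_tetrads(n, b, l, seed = 21, conditional = TRUE)
  k <- pair_kernel(b, l)
  # P(chrom disomic | spore viable) = p_disome (1-pb)^2 / marginal
  p_dis <- k$p_disome * (1 - l$pb)^2 / k$marginal
  obs <- s$chrom_counts$disomyAB / s$n_viable_spores
  for (c in seq_len(16))
    expect_lt(abs(obs[c] - p_dis[c]), three_se(p_dis[c], s$n_viable_spores) + 1e-9)
  # full disjunction of the longest chromosome forbids its disomy
  b1 <- yeast_bias(x_max = 1.0)
  s1 <- simulate_tetrads(5e4, b1, loss_params(0, 0), seed = 22, conditional = TRUE)
  expect_equal(s1$chrom_counts$disomyAB[s1$chrom_counts$name == "chr4"], 0)
})

test_that("unconditional simulator matches exhaustive enumeration on a 2-chromosome genome", {
  b <- tiny_bias(2, x_max = 0.8)
  pa <- 0.05; pb <- 0.1
  exact <- enumerate_unconditional(b, pa, pb)
  expect_equal(sum(exact), 1, tolerance = 1e-12)
  n <- 2e5
  s <- simulate_tetrads(n, b, loss_params(pa, pb), seed = 31)
  for (catg in names(exact)) {
    p <- unname(exact[catg])
    expect_lt(abs(s$categories[[catg]] / n - p), three_se(p, n) + 1e-9)
  }
})

test_that("conditional and unconditional runs estimate the same category ratios", {
  b <- yeast_bias()
  l <- loss_params(0.017, 0.013)
  cond <- simulate_tetrads(5e4, b, l, seed = 41, conditional = TRUE)
  unc <- simulate_tetrads(3e6, b, l, seed = 42)
  f_cond <- ascus_fractions(cond)
  f_unc <- ascus_fractions(unc)
  n_eff <- sum(unc$categories[c("copies", "altered_copies", "single", "mii_dead")])
  for (catg in c("copies", "single")) {
    expect_lt(abs(f_cond[[catg]] - f_unc[[catg]]),
              three_se(f_unc[[catg]], min(5e4, n_eff)) * 2)
  }
  # the recorded conditioning probability reconstructs unconditional scale
  expect_lt(abs(unc$categories[["mi_dead"]] / 3e6 - (1 - 2 * cond$p_full)),
            3e-3 + 3 * sqrt(cond$p_full / 3e6))
})
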
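test_that("full-daughter probability has its closed form at the corner cases", {
  expect_equal(p_daughter_full(yeast_bias()), (3 / 4)^16)
  # all chromosomes disjoin deterministically -> daughter always full
  b_disj <- compute_bias(sacCer3_chromosomes(), 1, 1, mode = "disjunction")
  expect_equal(p_daughter_full(b_disj), 1.0)
  # all chromosomes co-segregate -> full iff every pair landed on this side
  b_cos <- compute_bias(sacCer3_chromosomes(), 1, 1, mode = "co_segregation")
  expect_equal(p_daughter_full(b_cos), (1 / 2)^16)
})

test_that("pair kernel reproduces frozen hand-computed values", {
  b <- yeast_bias()
  k <- pair_kernel(b, loss_params(0, 0.013))
  # (2/3) + (1/3) [ (1-pb)^4 + 2 pb^2 (1-pb)^2 ], pb = 0.013
  expect_equal(k$identical[1], 0.9831115, tolerance = 1e-6)
  expect_true(all(abs(k$identical - k$identical[1]) < 1e-15)) # unbiased: equal
  k2 <- pair_kernel(b, loss_params(0.017, 0))
  # designated-spore marginal: (2/3)(1-pa) + 1/3
  expect_equal(k2$marginal[1], 0.9886667, tolerance = 1e-6)
  # kernel ordering invariant
  k3 <- pair_kernel(b, loss_params(0.02, 0.03))
  expect_true(all(k3$identical <= k3$both_viable + 1e-15))
  expect_true(all(k3$both_viable <= k3$marginal + 1e-15))
  expect_true(all(k3$marginal <= 1))
  expect_true(all(k3$identical >= 0))
  # no loss -> kernel collapses to 1
  k0 <- pair_kernel(b, loss_params(0, 0))
  expect_equal(k0$identical, rep(1, 16))
  expect_equal(k0$marginal, rep(1, 16))
})

test_that("category fractions sum to one and anchor the fitted parameters", {
  b <- yeast_bias()
  for (loss in list(loss_params(0, 0.013), loss_params(0.017, 0.013),
                    loss_params(0.03, 0.25), loss_params(0, 0))) {
    f <- category_fractions(b, loss)
    expect_equal(sum(f[c("copies", "altered_copies", "single", "mii_dead")]), 1,
                 tolerance = 1e-12)
  }
  # the two quantities matched against the dissection data
  expect_equal(pair_identity_fraction(b, loss_params(0, 0.013)),
               0.7628292, tolerance = 1e-6)
  expect_equal(unname(category_fractions(b, loss_params(0.017, 0.013))["pair_fraction"]),
               0.7143735, tolerance = 1e-6)
  f0 <- category_fractions(b, loss_params(0, 0))
  expect_equal(unname(f0["copies"]), 1)
  expect_equal(unname(f0["single"]), 0)
})

test_that("oracle equals exhaustive enumeration exactly on 1-3 chromosome genomes", {
  cases <- list(
    list(K = 1, pa = 0.1, pb = 0.2, x_max = 0.5, mode = "disjunction", pbm = "per_copy"),
    list(K = 2, pa = 0.017, pb = 0.013, x_max = 0.5, mode = "disjunction", pbm = "per_copy"),
    list(K = 2, pa = 0.05, pb = 0.1, x_max = 0.9, mode = "disjunction", pbm = "per_copy"),
    list(K = 3, pa = 0.02, pb = 0.08, x_max = 0.8, mode = "co_segregation", pbm = "per_copy"),
    list(K = 3, pa = 0.1, pb = 0.15, x_max = 0.7, mode = "disjunction", pbm = "lose_one"))
  for (cs in cases) {
    b <- tiny_bias(cs$K, x_max = cs$x_max, mode = cs$mode)
    f <- category_fractions(b, loss_params(cs$pa, cs$pb), pb_mode = cs$pbm)
    e <- enumerate_conditional(b, cs$pa, cs$pb, pb_mode = cs$pbm)
    expect_equal(unname(f[names(e)]), unname(e), tolerance = 1e-12)
  }
})

test_that("identity fraction decreases in pb and pair fraction decreases in pa", {
  b <- yeast_bias()
  idf <- vapply(seq(0, 0.3, by = 0.01),
                function(pb) pair_identity_fraction(b, loss_params(0, pb)),
                numeric(1))
  expect_true(all(diff(idf) <= 0))
  pf <- vapply(seq(0, 0.04, by = 0.002), function(pa)
    unname(category_fractions(b, loss_params(pa, 0.013))["pair_fraction"]),
    numeric(1))
  expect_true(all(diff(pf) <= 0))
})

test_that("lose-one pb convention cannot reproduce the printed identity target", {
  # under the alternative semantics the pb matching 20/26 is far from 1.3%
  b <- yeast_bias()
  id_at_0013 <- pair_identity_fraction(b, loss_params(0, 0.013), pb_mode = "lose_one")
  expect_gt(id_at_0013, 0.85) # nowhere near 0.769 at 1.3%
  grid <- seq(0, 0.05, by = 0.001)
  ids <- vapply(grid, function(pb)
    pair_identity_fraction(b, loss_params(0, pb), pb_mode = "lose_one"), numeric(1))
  best <- grid[which.min(abs(ids - 20 / 26))]
  expect_gt(best, 0.02) # ~2.4-2.5%, not 1.3%
})
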
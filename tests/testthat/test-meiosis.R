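test_that("MI segregation conserves two copies per chromosome", {
  set.seed(101)
  b <- tiny_bias(3, x_max = 0.9)
  for (i in 1:200) {
    d <- segregate_mi(b)
    copies <- copy_number(d[1, ]) + copy_number(d[2, ])
    expect_true(all(copies == 2))
  }
})

test_that("x = 1 under disjunction always splits the homologs", {
  set.seed(102)
  b <- compute_bias(tiny_table(2), x_min = 1, x_max = 1, n_expected = 2)
  for (i in 1:100) {
    d <- segregate_mi(b)
    expect_true(all(d %in% c("A", "B")))
    expect_true(all(d[1, ] != d[2, ]))
  }
})

test_that("unbiased same-pole frequency and full-daughter rate match closed forms", {
  set.seed(103)
  b <- yeast_bias()
  n <- 3000
  full <- logical(n)
  same_pole_events <- 0
  for (i in seq_len(n)) {
    d <- segregate_mi(b)
    same_pole_events <- same_pole_events + sum(d[1, ] %in% c("AB", "0"))
    full[i] <- all(d[1, ] != "0")
  }
  expect_lt(abs(same_pole_events / (16 * n) - 0.5), three_se(0.5, 16 * n))
  p <- (3 / 4)^16
  expect_lt(abs(mean(full) - p), three_se(p, n))
})

test_that("MII without loss mirrors the daughter composition", {
  set.seed(104)
  daughter <- c(chr1 = "AB", chr2 = "A", chr3 = "B")
  sp <- segregate_mii(daughter, loss_params(0, 0))
  expect_equal(unname(sp[1, ]), unname(daughter))
  expect_equal(unname(sp[2, ]), unname(daughter))
})

test_that("pb = 1 destroys every disome copy", {
  set.seed(105)
  sp <- segregate_mii(c(chr1 = "AB"), loss_params(0, 1))
  expect_true(all(sp == "0"))
  expect_false(spore_viable(sp[1, , drop = TRUE]))
})

test_that("per-copy disome loss frequencies match the binomial expansion", {
  pb <- 0.1 # inflated so the rare outcomes are observable
  # brute-force enumeration over the 4 (lose A) x (lose B) outcomes
  states <- c("AB", "A", "B", "0")
  brute <- c(AB = (1 - pb)^2, A = pb * (1 - pb), B = pb * (1 - pb), `0` = pb^2)
  o <- loss_outcomes("AB", pa = 0, pb = pb)
  expect_equal(setNames(o$p, o$state)[states], brute[states])

  set.seed(106)
  n <- 20000
  draws <- replicate(n, segregate_mii(c(c1 = "AB"), loss_params(0, pb))[1, 1])
  freq <- table(factor(draws, levels = states)) / n
  for (s in states)
    expect_lt(abs(freq[[s]] - brute[[s]]), three_se(brute[[s]], n) + 1e-9)
  # the spec'd small-pb case, against the same expansion
  pb2 <- 0.013
  o2 <- loss_outcomes("AB", 0, pb2)
  expect_equal(o2$p[o2$state == "AB"], 0.974169)
  expect_equal(sum(o2$p[o2$state %in% c("A", "B")]), 0.025662)
  expect_equal(o2$p[o2$state == "0"], 0.000169)
})

test_that("classification matches the category definitions exactly", {
  chroms <- paste0("chr", 1:2)
  mk <- function(...) { m <- rbind(...); colnames(m) <- chroms; m }
  d <- mk(c("AB", "A"), c("0", "B"))

  d_both_full <- mk(c("A", "A"), c("B", "B"))
  expect_equal(classify_tetrad(mk(c("A", "A"), c("A", "A"), c("B", "B"), c("B", "B")),
                               daughters = d_both_full), "multi")
  expect_equal(classify_tetrad(mk(c("A", "A"), c("A", "A"), c("B", "B"), c("B", "0")),
                               daughters = d_both_full), "multi")
  expect_equal(classify_tetrad(mk(c("AB", "A"), c("AB", "A"), c("0", "0"), c("0", "0")),
                               daughters = d), "copies")
  expect_equal(classify_tetrad(mk(c("AB", "A"), c("A", "A"), c("0", "0"), c("0", "0")),
                               daughters = d), "altered_copies")
  expect_equal(classify_tetrad(mk(c("AB", "A"), c("0", "A"), c("0", "0"), c("0", "0")),
                               daughters = d), "single")
  expect_equal(classify_tetrad(mk(c("0", "A"), c("0", "A"), c("0", "0"), c("0", "0")),
                               daughters = d), "mii_dead")
  d_none <- mk(c("AB", "0"), c("0", "AB"))
  expect_equal(classify_tetrad(mk(c("0", "0"), c("0", "0"), c("0", "0"), c("0", "0")),
                               daughters = d_none), "mi_dead")
})

test_that("no loss and one full daughter always yields identical copies", {
  set.seed(107)
  b <- tiny_bias(3)
  loss0 <- loss_params(0, 0)
  seen <- 0
  while (seen < 50) {
    d <- segregate_mi(b)
    full <- apply(d, 1, function(x) all(x != "0"))
    if (sum(full) != 1) next
    seen <- seen + 1
    spores <- rbind(segregate_mii(d[1, ], loss0), segregate_mii(d[2, ], loss0))
    expect_equal(classify_tetrad(spores, d), "copies")
  }
})

test_that("copy conservation holds through MII losses and no state exceeds two copies", {
  set.seed(108)
  b <- tiny_bias(3, x_max = 0.8)
  loss <- loss_params(0.1, 0.2)
  for (i in 1:200) {
    d <- segregate_mi(b)
    spores <- rbind(segregate_mii(d[1, ], loss), segregate_mii(d[2, ], loss))
    expect_true(all(spores %in% c("0", "A", "B", "AB")))
    total <- colSums(matrix(copy_number(spores), 4))
    expect_true(all(total <= 4))
    # parental copies are conserved or lost, never created
    for (ch in seq_len(3)) {
      a_in <- sum(d[, ch] %in% c("A", "AB"))
      a_out <- sum(spores[, ch] %in% c("A", "AB"))
      expect_lte(a_out, 2 * a_in)
    }
  }
})
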
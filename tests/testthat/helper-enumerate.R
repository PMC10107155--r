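# Independent exhaustive-enumeration oracles for reduced genomes. These walk
# every MI / MII / loss outcome with its exact probability and never call the
# simulator or the product-form oracle they are used to verify.

# per-spore loss outcome distribution given the MII-entry composition code
loss_outcomes <- function(comp, pa, pb, pb_mode = "per_copy") {
  if (comp == "AB") {
    if (pb_mode == "per_copy") {
      data.frame(state = c("AB", "A", "B", "0"),
                 p = c((1 - pb)^2, pb * (1 - pb), pb * (1 - pb), pb^2))
    } else {
      data.frame(state = c("AB", "A", "B"), p = c(1 - pb, pb / 2, pb / 2))
    }
  } else if (comp %in% c("A", "B")) {
    data.frame(state = c(comp, "0"), p = c(1 - pa, pa))
  } else {
    data.frame(state = "0", p = 1)
  }
}

# Exact ascus-category probabilities conditional on a designated full MI
# daughter, for any number of chromosomes.  Folds chromosomes over the joint
# distribution of (both spores identical so far, spore 1 viable, spore 2
# viable), which is sufficient to classify the two-spore ascus.
enumerate_conditional <- function(bias, pa, pb, pb_mode = "per_copy") {
  h <- bias$same_pole / 2
  p_dis <- h / (1 - h)
  # state probabilities indexed [eq, v1, v2], each TRUE/FALSE
  P <- array(0, c(2, 2, 2))
  P[2, 2, 2] <- 1 # eq = v1 = v2 = TRUE
  for (c in seq_along(p_dis)) {
    comp_dist <- data.frame(comp = c("AB", "A", "B"),
                            p = c(p_dis[c], (1 - p_dis[c]) / 2, (1 - p_dis[c]) / 2))
    Pn <- array(0, c(2, 2, 2))
    for (i in seq_len(nrow(comp_dist))) {
      o <- loss_outcomes(comp_dist$comp[i], pa, pb, pb_mode)
      for (a in seq_len(nrow(o))) for (b in seq_len(nrow(o))) {
        pr <- comp_dist$p[i] * o$p[a] * o$p[b]
        if (pr == 0) next
        eq <- o$state[a] == o$state[b]
        v1 <- o$state[a] != "0"; v2 <- o$state[b] != "0"
        for (E in 1:2) for (V1 in 1:2) for (V2 in 1:2) {
          if (P[E, V1, V2] == 0) next
          Pn[min(E, eq + 1), min(V1, v1 + 1), min(V2, v2 + 1)] <-
            Pn[min(E, eq + 1), min(V1, v1 + 1), min(V2, v2 + 1)] +
            P[E, V1, V2] * pr
        }
      }
    }
    P <- Pn
  }
  copies <- P[2, 2, 2]
  altered <- P[1, 2, 2]
  single <- P[2, 2, 1] + P[2, 1, 2] + P[1, 2, 1] + P[1, 1, 2]
  mii_dead <- P[2, 1, 1] + P[1, 1, 1]
  c(copies = copies, altered_copies = altered, single = single,
    mii_dead = mii_dead)
}

# Exact unconditional tetrad-category probabilities for a tiny genome by full
# expansion of every MI branch and every per-spore loss outcome; classifies
# each complete tetrad with the package classifier.
enumerate_unconditional <- function(bias, pa, pb, pb_mode = "per_copy") {
  K <- length(bias$same_pole)
  cn <- bias$same_pole
  # per chromosome: MI branch distribution over daughter compositions
  mi_branch <- function(c) {
    data.frame(d1 = c("AB", "0", "A", "B"),
               d2 = c("0", "AB", "B", "A"),
               p = c(cn[c] / 2, cn[c] / 2, (1 - cn[c]) / 2, (1 - cn[c]) / 2))
  }
  # per chromosome: joint outcome (4 spore states, daughter presence flags)
  chrom_outcomes <- function(c) {
    out <- list()
    br <- mi_branch(c)
    for (i in seq_len(nrow(br))) {
      o1 <- loss_outcomes(br$d1[i], pa, pb, pb_mode)
      o2 <- loss_outcomes(br$d2[i], pa, pb, pb_mode)
      for (a in seq_len(nrow(o1))) for (b in seq_len(nrow(o1)))
        for (x in seq_len(nrow(o2))) for (y in seq_len(nrow(o2))) {
          pr <- br$p[i] * o1$p[a] * o1$p[b] * o2$p[x] * o2$p[y]
          if (pr == 0) next
          out[[length(out) + 1]] <- list(
            p = pr, s = c(o1$state[a], o1$state[b], o2$state[x], o2$state[y]),
            d = c(br$d1[i], br$d2[i]))
        }
    }
    out
  }
  per_chrom <- lapply(seq_len(K), chrom_outcomes)
  idx <- expand.grid(lapply(per_chrom, seq_along))
  cats <- c(copies = 0, altered_copies = 0, single = 0, mii_dead = 0,
            mi_dead = 0, multi = 0)
  for (r in seq_len(nrow(idx))) {
    p <- 1
    spores <- matrix("0", 4, K)
    daughters <- matrix("0", 2, K)
    for (c in seq_len(K)) {
      o <- per_chrom[[c]][[idx[r, c]]]
      p <- p * o$p
      spores[, c] <- o$s
      daughters[, c] <- o$d
    }
    cat_name <- classify_tetrad(spores, daughters)
    cats[cat_name] <- cats[cat_name] + p
  }
  cats
}
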
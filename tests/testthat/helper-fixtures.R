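# Shared fixtures: genomes, bias objects and small synthetic cohorts, all
# built in code at test time.

yeast_bias <- function(x_max = 0.5, mode = "disjunction") {
  compute_bias(sacCer3_chromosomes(), x_min = 0.5, x_max = x_max, mode = mode)
}

# reduced genomes for enumeration-based checks
tiny_table <- function(K) {
  chromosome_table(paste0("chr", seq_len(K)),
                   seq(100000, by = 150000, length.out = K))
}

tiny_bias <- function(K, x_min = 0.5, x_max = 0.5, mode = "disjunction") {
  compute_bias(tiny_table(K), x_min, x_max, mode = mode, n_expected = K)
}

# a spore cohort matrix with known per-chromosome states
fixed_cohort <- function(chroms, states_list) {
  m <- do.call(rbind, states_list)
  colnames(m) <- chroms
  m
}

# binomial 3-standard-error tolerance for a proportion estimated from n draws
three_se <- function(p, n) 3 * sqrt(p * (1 - p) / n)
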
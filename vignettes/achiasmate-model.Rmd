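---
title: "Modelling aneuploid spore formation in achiasmate yeast meiosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling aneuploid spore formation in achiasmate yeast meiosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A *spo11*∆ diploid enters meiosis without crossovers, so homolog pairs have
no chiasmata to orient them on the MI spindle. The simulator makes four
assumptions:

1. **Random (optionally length-biased) MI segregation.** Per chromosome,
   the homologs disjoin to opposite poles with probability `x_N`; otherwise
   both move to the same pole, chosen with equal probability. `x_N` is
   affine in chromosome length between `x_min` (shortest chromosome) and
   `x_max` (longest); `x_min` is fixed at 0.5, the fully random value, and
   `x_max = 0.5` gives the unbiased model.
2. **Equational MII with accidental loss.** Each spore inherits one
   chromatid per homolog present in its MI daughter. Losses then apply
   once, independently per spore per chromosome, on that MII-entry state:
   a monosomic copy is lost with probability `Pa`; each copy of a
   heterodisome is lost with probability `Pb`.
3. **Viability = completeness.** A spore lives iff it retains at least one
   copy of every one of the 16 chromosomes. Viable spores are therefore
   haploids decorated with heterodisomies; no simulated spore ever carries
   more than two copies of a chromosome, and every disomy carries one
   homolog of each parent.
4. **No per-chromosome fitness effects.** All chromosomes are exchangeable
   except for length. Deviations between this null model and observed
   per-chromosome aneuploidy rates are the object of the downstream
   statistics (length correlation, dosage-sensitive-gene impact), not of
   the simulator.

Asci are classified by survivors: `copies` (two viable spores, identical
per-chromosome states including parental origin), `altered_copies` (two
viable, differing), `single`, `mii_dead` (an MI daughter was complete but
losses killed both its spores), `mi_dead` (neither daughter complete), and
`multi` (three or more survivors, requiring both daughters complete — an
event of order $2^{-16}$ that is reported but excluded from the
four-category ratios).

## Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `Pa` | MII loss probability per monosomic chromosome per spore | fitted (1.7%) | probability |
| `Pb` | MII loss probability per disome copy per spore | fitted (1.3%) | probability |
| `x_min` | disjunction probability, shortest chromosome | 0.5 (fixed) | probability |
| `x_max` | disjunction probability, longest chromosome | 0.5 | probability |
| grid step | resolution of the Pa/Pb grids | 0.001 | probability |

The grid step matches the precision at which the estimates are quoted
(0.1 percentage points); a finer grid would pretend to more precision than
the 26 observed pairs support.

### Two semantics of `Pb`

"Losing one of a disomic pair" admits two readings. The package's default
(`pb_mode = "per_copy"`) treats each of the two copies as an independent
Bernoulli(`Pb`) loss, so a disome stays intact with probability
$(1-P_b)^2$, becomes a monosome with probability $2P_b(1-P_b)$ (the fired
copy is the one lost, fixing the surviving parental origin), and kills the
spore with probability $P_b^2$. The alternative (`pb_mode = "lose_one"`)
loses one uniformly chosen copy with probability `Pb` and can never destroy
both. Only the per-copy convention is consistent with the pair of printed
anchors (identical-pair fraction 20/26 at `Pb` ≈ 1.3%): under `lose_one`
the same target is met only near 2.4–2.5%. Both are implemented; tests pin
the distinction.

### Direction of the length bias

The length-dependent probability could bias chromosomes toward
*disjunction* (opposite poles) or *co-segregation* (same pole). The package
defaults to `mode = "disjunction"`: longer chromosomes disjoin more
faithfully, which suppresses their disomy and shifts the modal number of
disomies per viable spore downward from 5 into the observed 2–4 range as
`x_max` rises toward 100% — the behaviour the fitted model is meant to
reproduce, plausibly driven by chiasma-independent pairing that strengthens
with length. The opposite reading is retained (`mode = "co_segregation"`)
for sensitivity analyses.

### The two fitting targets

`fit_loss_rates()` matches (i) `copies / (copies + altered_copies)` against
the observed 20/26 to fit `Pb` at `Pa = 0`, then (ii)
`(copies + altered_copies) / (copies + altered_copies + single)` — the
fraction of two-viable-spore asci among all viable-set asci — against the
observed 71.0% to fit `Pa`. The 71.0% figure is deliberately interpreted as
this pair fraction (not as the complementary single-spore share of the same
ratio): only that reading is monotone-consistent with a loss parameter near
1.7% under the model.

## The exact oracle

Conditional on a designated complete MI daughter, chromosome `N` is
heterodisomic with probability $p_N = (c_N/2)/(1-c_N/2)$, where
$c_N = 1 - x_N$ is the same-pole probability, and the two spores' fates are
independent across chromosomes. Exact per-chromosome kernels (probability
both spores retain the chromosome identically / at all / marginally) then
give closed forms for all category fractions as 16-fold products
(`pair_kernel()`, `category_fractions()`). The oracle:

* is verified against brute-force enumeration of *every* MI/MII/loss
  outcome on 1–3-chromosome genomes (tolerance $10^{-12}$) in the test
  suite, with the enumeration written independently of both the oracle and
  the simulator;
* verifies the stochastic simulator (3-binomial-SE agreement at $10^6$
  tetrads across parameter settings);
* anchors the fits: at `Pb = 1.3%` the exact identical-pair fraction is
  0.7628, and at `Pa = 1.7%, Pb = 1.3%` the exact pair fraction is 0.7144.

The oracle ignores the $2^{-16}$-order double-complete-daughter tetrads,
exactly as the simulator's four-category ratios do. Products are evaluated
in log space so extreme parameter values cannot underflow.

## Conditional simulation

Roughly 99% of unbiased unconditional tetrads are `mi_dead`
($1 - 2\,(3/4)^{16}$), so fitting simulates only tetrads with a complete
designated daughter, drawing its composition from the exact per-chromosome
conditional distribution and recording the analytic conditioning
probability $\prod_N (1 - c_N/2)$ so unconditional rates can be
reconstructed. Unconditional mode is retained and tested against the
conditional estimates. The bulk simulator is compiled (Rcpp) and uses R's
RNG stream, so `set.seed()` governs everything; categorical draws use a
single uniform against precomputed cumulative thresholds.

## The synthetic sequencing generator

`generate_snp_table()` + `simulate_reads()` emulate resequencing of spores
from a cross of two diverged parents: SNPs at 0.7% density distinguish the
parental genomes; per-1-kb-bin depth is Poisson with mean
`effective copies × 30` (30× per copy is this package's choice; the
original depth per spore is not critical to any threshold); per-SNP
parent-A read counts are Binomial with a symmetric substitution error
(default 0.2%). Partial (mosaic) copy loss within a clone enters as an
effective copy number $2-\varphi$. The default genome is a miniature one —
sacCer3 lengths rescaled affinely onto 30–230 kb, preserving order — which
leaves every bias value unchanged (the bias is affine in length) while
keeping a 200-spore round trip under a minute; full-scale lengths are one
argument away.

What the generator does **not** emulate: GC-content and mappability biases,
overdispersed depth, alignment artefacts, indels or de-novo SNVs, and
read-level data. Passing round-trip tests therefore demonstrates the
callers' logic under the stated noise model, not their robustness to every
artefact of real short-read data.

## Caller thresholds and degenerate inputs

The exact allele-fraction and coverage thresholds used on the real data are
not published, so the caller's bands are set midway between integer-copy
expectations and exposed in `caller_params()`: allele-fraction tolerance
δ = 0.15; monosome ratio band [0.75, 1.25]; disome band [1.75, 2.25];
`partial_reduction` strictly between the bands; `none` below 0.25. The
monosome-baseline chicken-and-egg (ratios need a baseline; the baseline
needs calls) is resolved by a two-pass scheme — provisional states from
allele fractions alone, then the baseline as the median depth of the
provisional monosomes. A spore with no monosomic chromosome at all falls
back, with a warning, to the mode of the per-chromosome depth distribution.

For passage stability, both profiles are normalized by the median depth of
the chromosomes monosomic at g-0 (median, not mean, so a baseline
chromosome that itself gained a copy cannot distort the normalization),
and the per-chromosome ratio is thresholded at 0.5 / 1.5 with strict
inequalities, as published. One consequence deserves honesty: in
*noise-free* synthetic data a complete disome-to-monosome loss yields a
ratio of exactly 0.5 — precisely on the threshold — because copy numbers
are integers; real losses are detected because measurement noise and
culture mosaicism scatter the ratio around 0.5 and the flagged cases are
those falling below. The tests assert the exact boundary value, the
detection of gains (ratio 2.0), zero false verdicts elsewhere, and
invariance of all verdicts to a global depth rescaling.

The recombination detector is deliberately minimal, intended for the
no-recombination null of achiasmate spores: isolated single-SNP flips are
noise; an internal opposite-parent run spanning ≤ 10 kb is a gene
conversion; a remaining switch flanked by ≥ 20 concordant SNPs on both
sides is a crossover. Heterodisomic chromosomes are unphased and skipped
with a warning. This is not a general-purpose crossover caller — it has no
double-crossover-in-tract or CO-associated-conversion classes.

## Cohort statistics

`count_aneuploidies()` tallies disomies per chromosome (counting
`partial_reduction` as disomic at formation), normalizes by length
(counts/Mbp), and `band_subset()` selects the 10–25 counts/Mbp band used
before the length regression. The dosage-sensitive-gene impact of a
chromosome is $\sum_g 1/\mathrm{limit}(g)$; `log_association()` correlates
counts with `ln(impact)` (the transform applied to the impact side; taking
logs of both is available via `transform = "ln_both"`, since the exact
published transform is ambiguous). The packaged DSG table is a clearly
labelled synthetic fixture; the experimentally derived table it mimics is
external data, loadable through the same TSV format.

## Problem sizes and determinism

Defaults used by the shipped tests and scripts, chosen to keep a full run
on one CPU in minutes while leaving Monte-Carlo error far below every
decision margin: $10^6$ conditional tetrads per grid point for the headline
fits (identity-fraction SE ≈ $4\times10^{-4}$ against a per-grid-step
separation of ≈ $1.6\times10^{-2}$), $2\times10^5$ for exploratory fits,
200 spores for caller round trips. Every stochastic entry point takes a
seed; the end-to-end pipeline derives per-stage seeds from one top-level
seed and writes an md5 manifest, making each output byte-reproducible.

## Known limitations

* The diploid-euploid (MI-bypass) spore class is not modelled; such spores
  appear in real dissections but are outside this model's state space.
* `Pa`/`Pb` are applied once, at MII entry: a `Pb`-created monosome is not
  re-exposed to `Pa`. Chained losses are second-order at the fitted values
  (≈ $2P_aP_b \approx 4\times10^{-4}$ per disome).
* The tetrad classifier compares full states including parental origin;
  dissection data scored by karyotype only would merge a vanishing fraction
  of `altered_copies` into `copies`.
* The fitted values inherit the granularity of the observed counts (26
  pairs); the package reports grid estimates, not confidence intervals.
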
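Package: achiasmate
Title: Aneuploidy Formation and Detection in Achiasmate Yeast Meiosis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Stochastic simulation of chromosome segregation in budding-yeast
    meiosis lacking crossovers (spo11 deletion), with meiosis-II
    chromosome-loss probabilities for monosomes (Pa) and disome copies (Pb)
    and a chromosome-length-dependent meiosis-I segregation bias. Provides
    exact product-form probabilities for ascus-category frequencies, grid
    fitting of the loss parameters to observed tetrad dissection data,
    synthetic hybrid-diploid spore sequencing profiles with known karyotypes,
    per-chromosome ploidy and parental-origin calling from SNP allele
    fractions and binned read coverage, mitotic-passage stability
    classification, a simplified crossover/gene-conversion detector, and
    cohort-level aneuploidy statistics including dosage-sensitive-gene
    impact scores.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
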
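# End-to-end synthetic pipeline: simulate a spore cohort at given loss
# parameters, emulate sequencing, call karyotypes back, compute cohort
# statistics and re-fit the loss parameters from the simulated ascus counts.

#' Configuration for the end-to-end pipeline
#'
#' All stochastic stages derive their streams from the single top-level
#' `seed`; the configuration is serialized alongside the outputs so every
#' file is re-derivable.
#'
#' @param seed top-level integer seed.
#' @param pa,pb generating MII loss probabilities.
#' @param x_max,mode segregation-bias settings (see [compute_bias()]).
#' @param n_tetrads conditional tetrads for the ascus-category stage.
#' @param n_spores viable spores to sequence.
#' @param table chromosome table; the miniature genome by default.
#' @param snp_density parental SNP density.
#' @param mean_depth_per_copy,error_rate,bin_size sequencing-emulation knobs.
#' @param fit_n conditional tetrads per grid point when re-fitting.
#' @param pb_grid,pa_grid fitting grids.
#' @param caller caller thresholds ([caller_params()]).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, pa = 0.017, pb = 0.013, x_max = 0.5,
                       mode = "disjunction", n_tetrads = 2e5, n_spores = 69,
                       table = mini_chromosomes(), snp_density = 0.007,
                       mean_depth_per_copy = 30, error_rate = 0.002,
                       bin_size = 1000, fit_n = 2e4,
                       pb_grid = seq(0, 0.03, by = 0.001),
                       pa_grid = seq(0, 0.04, by = 0.001),
                       caller = caller_params()) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Run the full synthetic pipeline
#'
#' Stages, each seeded from the top-level seed:
#' \enumerate{
#'   \item simulate conditional tetrads at the generating `(Pa, Pb)` and
#'     record the ascus-category counts;
#'   \item sample a cohort of viable spores and write their true karyotypes;
#'   \item generate a parental SNP map and per-spore read profiles;
#'   \item call each spore's karyotype back from its profile;
#'   \item cohort statistics: aneuploidy counts, band subset, length
#'     correlation, DSG impact association, parental bias;
#'   \item re-fit `(Pa, Pb)` from the simulated ascus fractions.
#' }
#' A JSON report plus TSV tables and an md5 manifest are written to
#' `out_dir`; the run is byte-reproducible given the configuration.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results (`sim`,
#'   `karyotypes`, `calls`, `counts`, `fit`, `report`).
#' @export
run_end_to_end <- function(config = run_config(), out_dir = tempfile("achiasmate_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- config$seed + 0:5 * 1000L

  bias <- compute_bias(config$table, x_min = 0.5, x_max = config$x_max,
                       mode = config$mode)
  loss <- loss_params(pa = config$pa, pb = config$pb)

  # 1. ascus categories
  sim <- simulate_tetrads(config$n_tetrads, bias, loss, seed = seeds[1],
                          conditional = TRUE)
  fr <- ascus_fractions(sim)

  # 2. spore cohort
  karyo <- sample_viable_spores(config$n_spores, bias, loss, seed = seeds[2])
  write_karyotypes(karyo, file.path(out_dir, "karyotypes.tsv"))

  # 3. sequencing emulation + 4. calling
  snps <- generate_snp_table(config$table, config$snp_density, seed = seeds[3])
  set.seed(seeds[4])
  calls_list <- lapply(seq_len(config$n_spores), function(i) {
    truth <- ground_truth(setNames(karyo[i, ], colnames(karyo)))
    prof <- simulate_reads(truth, snps, config$table,
                           mean_depth_per_copy = config$mean_depth_per_copy,
                           error_rate = config$error_rate,
                           bin_size = config$bin_size)
    calls <- call_karyotype(prof, snps, config$caller)
    cbind(sample = sprintf("spore%03d", i), calls)
  })
  calls <- do.call(rbind, calls_list)
  write.table(calls, file.path(out_dir, "calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # 5. cohort statistics
  counts <- count_aneuploidies(calls, config$table)
  write.table(counts, file.path(out_dir, "aneuploidy_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  band <- band_subset(counts)
  lc <- tryCatch(length_correlation(counts,
                                    subset = if (length(band) >= 3) band else NULL),
                 error = function(e) NULL)
  dsgs <- read_dsg_table()
  imp <- dsg_impact(dsgs, config$table)
  la <- tryCatch(log_association(counts, imp), error = function(e) NULL)
  pbias <- parental_bias(calls)

  # 6. parameter re-fit from the simulated ascus fractions
  fit <- fit_loss_rates(identical_pairs = unname(sim$categories["copies"]),
                        viable_pairs = unname(sim$categories["copies"] +
                                              sim$categories["altered_copies"]),
                        pair_fraction = unname(fr["pair_fraction"]),
                        bias = bias, pb_grid = config$pb_grid,
                        pa_grid = config$pa_grid, n = config$fit_n,
                        seed = seeds[5])

  call_accuracy <- {
    truth_codes <- as.vector(t(karyo))
    called_codes <- c(none = "0", monoA = "A", monoB = "B", disomyAB = "AB",
                      partial_reduction = "AB")[calls$state]
    mean(called_codes == truth_codes)
  }

  report <- list(
    config = config[setdiff(names(config), c("table", "caller"))],
    chromosomes = config$table,
    ascus_categories = as.list(sim$categories),
    ascus_fractions = as.list(fr),
    disomy_hist = as.list(sim$disomy_hist),
    caller_accuracy = call_accuracy,
    band_subset = band,
    length_correlation = if (!is.null(lc)) list(r_subset = lc$r_subset,
                                                r_all = lc$r_all) else NULL,
    dsg_log_association = if (!is.null(la)) la$r else NULL,
    parental_bias_overall = pbias$overall,
    fitted = list(pa = fit$pa, pb = fit$pb,
                  generating = list(pa = config$pa, pb = config$pb)),
    outputs = c("karyotypes.tsv", "calls.tsv", "aneuploidy_counts.tsv"))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  invisible(list(sim = sim, karyotypes = karyo, calls = calls,
                 counts = counts, fit = fit, report = report,
                 out_dir = out_dir))
}
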
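# Plain-text readers/writers for the package's tabular interfaces: karyotype
# TSV, bedGraph-like coverage, allele-depth TSV, minimal VCF, and JSON
# simulation summaries.

#' Write / read a spore karyotype table
#'
#' One row per spore, one column per chromosome, values in
#' `{0, A, B, AB, AA, BB}`.
#'
#' @param karyotypes character matrix (spores x chromosomes).
#' @param path file path.
#' @return `read_karyotypes` returns the character matrix.
#' @export
write_karyotypes <- function(karyotypes, path) {
  d <- as.data.frame(karyotypes, stringsAsFactors = FALSE)
  d <- cbind(spore = seq_len(nrow(d)), d)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_karyotypes
#' @export
read_karyotypes <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, setdiff(names(d), "spore"), drop = FALSE])
  rownames(m) <- NULL
  m
}

#' Write / read binned coverage as bedGraph-like TSV
#'
#' Four columns without header: chrom, 0-based start, end, depth.
#'
#' @param coverage data.frame with columns `chrom`, `start`, `end`, `depth`.
#' @param path file path.
#' @export
write_coverage_tsv <- function(coverage, path) {
  write.table(coverage[, c("chrom", "start", "end", "depth")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_coverage_tsv
#' @export
read_coverage_tsv <- function(path) {
  d <- read.delim(path, header = FALSE,
                  col.names = c("chrom", "start", "end", "depth"),
                  stringsAsFactors = FALSE)
  d
}

#' Write / read per-SNP parental allele depths as TSV
#'
#' Columns: `chrom`, `pos` (1-based), `countA`, `countB`.
#'
#' @param alleles data.frame with those columns.
#' @param path file path.
#' @export
write_allele_tsv <- function(alleles, path) {
  write.table(alleles[, c("chrom", "pos", "countA", "countB")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_allele_tsv
#' @export
read_allele_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Assemble a read profile from files
#'
#' @param coverage_path bedGraph-like coverage TSV.
#' @param allele_path allele-depth TSV.
#' @return A `read_profile`.
#' @export
read_profile_tsv <- function(coverage_path, allele_path) {
  coverage <- read_coverage_tsv(coverage_path)
  alleles <- read_allele_tsv(allele_path)
  bin <- if (nrow(coverage)) coverage$end[1] - coverage$start[1] else NA
  structure(list(coverage = coverage, alleles = alleles, bin_size = bin,
                 mean_depth_per_copy = NA),
            class = "read_profile")
}

#' Write per-SNP allele depths as a minimal VCF
#'
#' Emits a VCF v4.2 file with one sample and `GT:AD` fields: parent A's
#' allele as REF, parent B's as ALT, and the AD field carrying the
#' (countA, countB) read depths.
#'
#' @param snps a [generate_snp_table()] SNP map.
#' @param alleles matching allele-depth data.frame (`chrom`, `pos`,
#'   `countA`, `countB`).
#' @param path output path.
#' @param sample sample name.
#' @export
write_allele_vcf <- function(snps, alleles, path, sample = "spore") {
  key <- paste(alleles$chrom, alleles$pos)
  idx <- match(paste(snps$chrom, snps$pos), key)
  if (anyNA(idx)) stop("allele depths do not cover all SNP sites")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", sample, sep = "\t"))
  ca <- alleles$countA[idx]; cb <- alleles$countB[idx]
  gt <- ifelse(ca > 0 & cb > 0, "0/1", ifelse(cb > 0, "1/1", "0/0"))
  body <- paste(snps$chrom, snps$pos, ".", snps$alleleA, snps$alleleB, ".",
                "PASS", ".", "GT:AD",
                paste0(gt, ":", ca, ",", cb), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read per-SNP allele depths from a minimal VCF
#'
#' Uses the vcfR package (Suggests) to parse a VCF with an `AD` format field
#' and returns the `chrom`/`pos`/`countA`/`countB` allele-depth table, REF
#' read counts as `countA`.
#'
#' @param path VCF path (uncompressed).
#' @return Allele-depth data.frame.
#' @export
read_allele_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package; use the TSV interface otherwise")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")[, 1]
  parts <- strsplit(ad, ",", fixed = TRUE)
  data.frame(chrom = as.character(v@fix[, "CHROM"]),
             pos = as.integer(v@fix[, "POS"]),
             countA = as.integer(vapply(parts, `[`, "", 1)),
             countB = as.integer(vapply(parts, `[`, "", 2)),
             stringsAsFactors = FALSE)
}

#' Write a tetrad-simulation summary as JSON
#'
#' @param sim a `tetrad_sim` object.
#' @param path output path.
#' @export
write_simulation_json <- function(sim, path) {
  out <- list(categories = as.list(sim$categories),
              disomy_hist = as.list(sim$disomy_hist),
              chrom_counts = sim$chrom_counts,
              n_viable_spores = sim$n_viable_spores,
              n_tetrads = sim$n_tetrads,
              p_full = sim$p_full,
              conditional = sim$conditional,
              pb_mode = sim$pb_mode,
              params = list(pa = sim$loss$pa, pb = sim$loss$pb,
                            x_min = sim$bias$x_min, x_max = sim$bias$x_max,
                            mode = sim$bias$mode),
              seed = sim$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
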
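#' Run the full divergence scan on a population pair
#'
#' End-to-end orchestration: per-site FST table, windowed statistics at the
#' scan window size and at the (larger) Tajima's-D window size, outlier
#' detection (empirical top quantile intersected with the permutation-FDR
#' test), region building (merge, barrier-strength boundary refinement,
#' coverage filter) and four-way classification of the refined regions.
#'
#' @param pop1,pop2 [genotype_matrix()] objects over identical loci.
#' @param mask accessible intervals (chrom, start, end; 0-based half-open)
#'   or `NULL`.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param window_size scan window size (default 10 kb).
#' @param td_window_size window size for the genome-wide Tajima's D
#'   distribution used by the classifier (default 100 kb).
#' @param maf_threshold pooled MAF threshold for the FST scan (default 0.25).
#' @param top_q empirical tail fraction (default 0.01).
#' @param fdr FDR level for the permutation branch (default 0.01).
#' @param n_perm number of site permutations (default 10000; the faithful
#'   full-scale setting is 1e6).
#' @param seed integer seed for the permutations.
#' @param threshold_mode `"per-pop"` or `"shared"` classifier thresholds.
#' @param labels length-2 population labels (e.g. `c("lake", "river")`).
#' @param ... passed to [build_regions()].
#' @return List of class `divergence_scan` with elements `sites`, `windows`,
#'   `td_windows`, `genome_fst`, `thresholds`, `regions` (classified) and the
#'   scan parameters.
#' @export
divergence_scan <- function(pop1, pop2, mask = NULL, chrom_lengths,
                            window_size = 10000, td_window_size = 100000,
                            maf_threshold = 0.25, top_q = 0.01, fdr = 0.01,
                            n_perm = 10000, seed = 1L,
                            threshold_mode = "per-pop",
                            labels = c("pop1", "pop2"), ...) {
  sites <- site_fst_table(pop1, pop2, maf_threshold)
  windows <- window_stats(pop1, pop2, mask, window_size, chrom_lengths,
                          maf_threshold)
  td_windows <- window_stats(pop1, pop2, mask, td_window_size, chrom_lengths,
                             maf_threshold)
  genome_fst <- mean(sites$fst[sites$retained], na.rm = TRUE)
  windows <- scan_outliers(windows, sites, q = top_q, fdr = fdr,
                           n_perm = n_perm, seed = seed)
  outl <- windows[windows$final_flag, c("chrom", "start", "end")]
  regions <- build_regions(outl, sites, genome_fst, mask, chrom_lengths, ...)
  thresholds <- compute_thresholds(td_windows$td_pop1, td_windows$td_pop2,
                                   mode = threshold_mode)
  regions <- classify_regions(regions, pop1, pop2, thresholds, labels)
  structure(list(sites = sites, windows = windows, td_windows = td_windows,
                 genome_fst = genome_fst, thresholds = thresholds,
                 regions = regions,
                 params = list(window_size = window_size,
                               td_window_size = td_window_size,
                               maf_threshold = maf_threshold, top_q = top_q,
                               fdr = fdr, n_perm = n_perm, seed = seed,
                               threshold_mode = threshold_mode,
                               labels = labels)),
            class = "divergence_scan")
}

#' @export
print.divergence_scan <- function(x, ...) {
  cat(sprintf(paste0("divergence_scan: %d windows (%d outliers), ",
                     "%d divergent regions, genome-wide FST %.3f\n"),
              nrow(x$windows), sum(x$windows$final_flag),
              nrow(x$regions), x$genome_fst))
  if (nrow(x$regions)) print(table(x$regions$category))
  invisible(x)
}

#' Run the pipeline from files and write a report bundle
#'
#' Reads a VCF + popmap + mask, runs [divergence_scan()], and writes the
#' window table, outlier windows (TSV + BED), classified regions (TSV + BED6
#' with the category in the name column) and a per-pair summary, each with a
#' header recording the package version, seed and configuration hash. When a
#' gene annotation is configured, per-region gene overlaps are added.
#'
#' @param config named list (or path to a YAML file) with entries: `vcf`,
#'   `popmap`, `mask` (paths; `mask` may be `NULL`), optional `genes`
#'   (GFF3/BED path), `out_dir`, and any of the [divergence_scan()]
#'   parameters (`window_size`, `td_window_size`, `maf_threshold`, `top_q`,
#'   `fdr`, `n_perm`, `seed`, `threshold_mode`, `labels`, `chrom_lengths`).
#' @return The `divergence_scan` result, invisibly; files are written to
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (field in c("vcf", "popmap", "out_dir")) {
    if (is.null(config[[field]])) stop("config is missing required field: ", field)
  }
  for (field in c("vcf", "popmap", "mask", "genes")) {
    if (!is.null(config[[field]]) && !file.exists(config[[field]])) {
      stop("config field '", field, "' points to a missing file: ",
           config[[field]])
    }
  }
  mask <- if (!is.null(config$mask)) read_bed(config$mask) else NULL
  pair <- read_vcf_pair(config$vcf, config$popmap, mask)
  chrom_lengths <- config$chrom_lengths
  if (is.null(chrom_lengths)) {
    mx <- tapply(pair$pop1$pos, pair$pop1$chrom, max)
    chrom_lengths <- stats::setNames(as.double(mx), names(mx))
  } else {
    chrom_lengths <- unlist(chrom_lengths)
  }
  args <- config[intersect(names(config),
                           c("window_size", "td_window_size", "maf_threshold",
                             "top_q", "fdr", "n_perm", "seed",
                             "threshold_mode", "labels"))]
  if (!is.null(args$labels)) args$labels <- unlist(args$labels)
  scan <- do.call(divergence_scan,
                  c(list(pop1 = pair$pop1, pop2 = pair$pop2, mask = mask,
                         chrom_lengths = chrom_lengths), args))
  if (!is.null(config$genes)) {
    scan$regions <- intersect_genes(scan$regions, config$genes)
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(divscan = as.character(utils::packageVersion("divscan")),
           seed = as.character(scan$params$seed),
           config_hash = config_hash(config))
  outp <- function(f) file.path(config$out_dir, f)
  write_tsv(scan$windows, outp("windows.tsv"), hdr)
  outl <- scan$windows[scan$windows$final_flag, , drop = FALSE]
  write_tsv(outl, outp("outlier_windows.tsv"), hdr)
  write_bed(outl[, c("chrom", "start", "end")], outp("outlier_windows.bed"), hdr)
  write_tsv(scan$regions, outp("regions.tsv"), hdr)
  reg_bed <- scan$regions[, c("chrom", "start", "end")]
  reg_bed$name <- scan$regions$category
  write_bed(reg_bed, outp("regions.bed"), hdr)
  labels <- scan$params$labels
  write_tsv(summarize_categories(scan$regions, pair = "pair1", labels = labels),
            outp("summary.tsv"), hdr)
  log_lines <- c(sprintf("divscan %s", hdr[["divscan"]]),
                 sprintf("seed: %s  config_hash: %s", hdr[["seed"]],
                         hdr[["config_hash"]]),
                 sprintf("sites loaded: %d", nrow(scan$sites)),
                 sprintf("sites retained by MAF >= %.2f: %d",
                         scan$params$maf_threshold, sum(scan$sites$retained)),
                 sprintf("windows: %d  empirical outliers: %d  final outliers: %d",
                         nrow(scan$windows), sum(scan$windows$empirical_flag),
                         sum(scan$windows$final_flag)),
                 sprintf("divergent regions after coverage filter: %d",
                         nrow(scan$regions)))
  writeLines(log_lines, outp("run.log"))
  invisible(scan)
}

# stable md5 of the analytic configuration (the output location is excluded
# so reruns into different directories hash identically)
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  flat <- config[setdiff(names(config), "out_dir")]
  flat <- flat[order(names(flat))]
  writeLines(paste(names(flat), vapply(flat, function(x)
    paste(format(unlist(x)), collapse = ","), character(1)), sep = "="), tf)
  unname(tools::md5sum(tf))
}
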
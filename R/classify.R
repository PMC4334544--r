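#' Genome-wide Tajima's D quantile thresholds for region classification
#'
#' Computes, per population, the empirical 5% and 95% quantiles (type 7) of
#' the genome-wide windowed Tajima's D distribution. In `"shared"` mode the
#' two populations' window values are pooled and both populations use the
#' same thresholds (a robustness variant).
#'
#' @param td_pop1,td_pop2 Tajima's D values of genome-wide windows (typically
#'   100 kb) for each population; `NA` windows are dropped.
#' @param mode `"per-pop"` (default) or `"shared"`.
#' @param min_windows minimum non-missing windows required (default 100).
#' @return List with numeric vectors `q05` and `q95`, each of length 2
#'   (population 1 and 2), and the `mode`.
#' @export
compute_thresholds <- function(td_pop1, td_pop2, mode = c("per-pop", "shared"),
                               min_windows = 100L) {
  mode <- match.arg(mode)
  v1 <- td_pop1[!is.na(td_pop1)]; v2 <- td_pop2[!is.na(td_pop2)]
  if (length(v1) < min_windows || length(v2) < min_windows) {
    stop("need at least ", min_windows, " non-missing windows per population")
  }
  if (mode == "shared") v1 <- v2 <- c(v1, v2)
  q <- function(v) stats::quantile(v, c(0.05, 0.95), names = FALSE, type = 7)
  q1 <- q(v1); q2 <- q(v2)
  list(q05 = c(q1[1], q2[1]), q95 = c(q1[2], q2[2]), mode = mode)
}

#' Classify a divergent region from its two Tajima's D values
#'
#' Rule table (thresholds from [compute_thresholds()]):
#' both below q05 = background selection; below q05 in only one population =
#' adaptation in that population (a sweep locally reduced its effective
#' population size); both within \[q05, q95\] = reduced gene flow (neutral
#' spectra despite elevated divergence); any remaining pattern (a value above
#' q95 with neither below q05), or a missing value, = unclassified.
#'
#' @param td_pop1,td_pop2 region Tajima's D per population (vectorized).
#' @param thresholds from [compute_thresholds()].
#' @param labels length-2 population labels used to name the adaptation
#'   categories (default `c("pop1", "pop2")`).
#' @return Character vector of categories.
#' @export
classify_region <- function(td_pop1, td_pop2, thresholds,
                            labels = c("pop1", "pop2")) {
  lo1 <- td_pop1 < thresholds$q05[1]
  lo2 <- td_pop2 < thresholds$q05[2]
  mid1 <- td_pop1 >= thresholds$q05[1] & td_pop1 <= thresholds$q95[1]
  mid2 <- td_pop2 >= thresholds$q05[2] & td_pop2 <= thresholds$q95[2]
  out <- rep("unclassified", max(length(td_pop1), length(td_pop2)))
  out[lo1 & lo2] <- "background_selection"
  out[lo1 & !lo2] <- paste0("adaptation_", labels[1])
  out[!lo1 & lo2] <- paste0("adaptation_", labels[2])
  out[mid1 & mid2] <- "reduced_gene_flow"
  out[is.na(td_pop1) | is.na(td_pop2)] <- "unclassified"
  out
}

#' Tajima's D of each region over its exact extent
#'
#' @param regions data frame of regions (chrom, start, end; half-open).
#' @param gm a [genotype_matrix()] for one population.
#' @return Numeric vector: region Tajima's D (`NA` with < 3 segregating sites).
#' @export
region_tajima_d <- function(regions, gm) {
  cc <- allele_counts(gm)
  vapply(seq_len(nrow(regions)), function(i) {
    sel <- gm$chrom == regions$chrom[i] &
      gm$pos > regions$start[i] & gm$pos <= regions$end[i]
    tajimas_d(cc$ac[sel], cc$an[sel])
  }, numeric(1))
}

#' Classify all divergent regions of a pair
#'
#' Computes each region's Tajima's D per population over its exact refined
#' extent and applies [classify_region()].
#'
#' @param regions data frame of refined regions.
#' @param pop1,pop2 [genotype_matrix()] objects.
#' @param thresholds from [compute_thresholds()].
#' @param labels population labels for the adaptation categories.
#' @return `regions` with `td_pop1`, `td_pop2` and `category` appended.
#' @export
classify_regions <- function(regions, pop1, pop2, thresholds,
                             labels = c("pop1", "pop2")) {
  regions$td_pop1 <- region_tajima_d(regions, pop1)
  regions$td_pop2 <- region_tajima_d(regions, pop2)
  regions$category <- classify_region(regions$td_pop1, regions$td_pop2,
                                      thresholds, labels)
  regions
}

#' Per-pair summary of classified divergent regions
#'
#' @param regions classified regions (with `size_kb`, `mean_fst`, `category`).
#' @param pair pair label for the summary row.
#' @param labels population labels used in the adaptation category names.
#' @return One-row data frame with region count, size and FST summaries and
#'   per-category counts.
#' @export
summarize_categories <- function(regions, pair = "pair1",
                                 labels = c("pop1", "pop2")) {
  cats <- c("background_selection", paste0("adaptation_", labels[1]),
            paste0("adaptation_", labels[2]), "reduced_gene_flow",
            "unclassified")
  counts <- vapply(cats, function(cc) sum(regions$category == cc), numeric(1))
  out <- data.frame(pair = pair, n_regions = nrow(regions),
                    mean_fst = if (nrow(regions)) mean(regions$mean_fst) else NA_real_,
                    mean_size_kb = if (nrow(regions)) mean(regions$size_kb) else NA_real_,
                    max_size_kb = if (nrow(regions)) max(regions$size_kb) else NA_real_,
                    sum_size_kb = sum(regions$size_kb),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(as.list(counts)))
}

#' Aggregate category counts across population pairs
#'
#' Given per-pair region totals and per-category counts, computes the
#' aggregate percentage of each category (category sum divided by the total
#' region count, rounded to the nearest integer percent; the two adaptation
#' categories are also reported combined) and the per-pair
#' reduced-gene-flow percentage range.
#'
#' @param counts data frame with columns `pair`, `n_regions`,
#'   `background_selection`, two `adaptation_*` columns and
#'   `reduced_gene_flow`.
#' @return List with `total_regions`, `pct` (named integer percentages) and
#'   `rgf_pct_range` (per-pair reduced-gene-flow percentage min and max).
#' @export
aggregate_category_counts <- function(counts) {
  if (!nrow(counts)) {
    return(list(total_regions = 0L, pct = integer(0),
                rgf_pct_range = c(NA_real_, NA_real_)))
  }
  adapt_cols <- grep("^adaptation_", names(counts), value = TRUE)
  total <- sum(counts$n_regions)
  pct_of <- function(x) as.integer(round(100 * sum(x) / total))
  pct <- c(background_selection = pct_of(counts$background_selection),
           adaptation = pct_of(rowSums(counts[, adapt_cols, drop = FALSE])),
           reduced_gene_flow = pct_of(counts$reduced_gene_flow))
  rgf_pct <- round(100 * counts$reduced_gene_flow / counts$n_regions)
  list(total_regions = total, pct = pct,
       rgf_pct_range = range(rgf_pct))
}
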
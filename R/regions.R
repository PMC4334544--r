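#' Merge adjacent outlier windows into candidate regions
#'
#' Maximal runs of outlier windows that share a boundary on the same
#' chromosome become one candidate; isolated outliers remain single-window
#' candidates.
#'
#' @param outlier_windows data frame with chrom, start, end (half-open),
#'   sorted by chromosome and start.
#' @return Data frame of candidate regions (chrom, start, end).
#' @export
merge_adjacent <- function(outlier_windows) {
  w <- outlier_windows
  if (!nrow(w)) return(data.frame(chrom = character(), start = double(),
                                  end = double(), stringsAsFactors = FALSE))
  if (is.unsorted(order(w$chrom, w$start))) stop("windows must be sorted")
  if (any(diff(w$start) <= 0 & w$chrom[-1] == w$chrom[-nrow(w)])) {
    stop("windows must be sorted by chromosome and start")
  }
  new_run <- c(TRUE, !(w$chrom[-1] == w$chrom[-nrow(w)] &
                         w$start[-1] == w$end[-nrow(w)]))
  run <- factor(cumsum(new_run), levels = unique(cumsum(new_run)))
  data.frame(chrom = as.character(tapply(w$chrom, run, `[`, 1)),
             start = as.double(tapply(w$start, run, min)),
             end = as.double(tapply(w$end, run, max)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Barrier strength of a local bin relative to the genome-wide average
#'
#' `b` contrasts local divergence to the genome-wide average as the ratio of
#' effective-migration odds: `b = [f/(1-f)] / [F/(1-F)]` for bin FST `f` and
#' genome-wide FST `F`. `b = 1` exactly when the bin equals the genome-wide
#' average; `b > 1` marks locally elevated divergence. A plain ratio `f/F` is
#' available via `formula = "ratio"`.
#'
#' @param bin_fst per-bin FST in \[0, 1\].
#' @param genome_fst genome-wide FST in (0, 1).
#' @param formula `"odds"` (default) or `"ratio"`.
#' @return Numeric vector of b values (`Inf` where `bin_fst = 1`).
#' @export
barrier_strength <- function(bin_fst, genome_fst, formula = c("odds", "ratio")) {
  formula <- match.arg(formula)
  if (!(genome_fst > 0 && genome_fst < 1)) stop("genome_fst must be in (0,1)")
  bin_fst <- pmax(bin_fst, 0)
  if (formula == "ratio") return(bin_fst / genome_fst)
  ifelse(bin_fst >= 1, Inf,
         (bin_fst / (1 - bin_fst)) / (genome_fst / (1 - genome_fst)))
}

#' Refine a candidate region's borders with a 1 kb barrier-strength walk
#'
#' The locus of maximal per-site FST within the candidate (leftmost on ties)
#' seeds the walk. From the peak's 1 kb bin, contiguous 1 kb bins are visited
#' outward on each side; a side's margin is set at the inner edge of the
#' first of two consecutive bins whose barrier strength drops below 1. Bins
#' without retained sites count as below threshold. The walk is clamped to
#' the chromosome and to `max_extension` bp per side.
#'
#' @param candidate one-row data frame (chrom, start, end; half-open).
#' @param sites per-site FST table ([site_fst_table()]) of retained sites for
#'   the whole chromosome (rows with `retained == FALSE` are ignored).
#' @param genome_fst genome-wide mean per-site FST.
#' @param chrom_length length of the candidate's chromosome in bp.
#' @param bin bin width in bp (default 1000).
#' @param max_extension maximum walk distance per side in bp (default 5e5).
#' @param formula barrier-strength formula, see [barrier_strength()].
#' @return One-row data frame (chrom, start, end, peak_pos, mean_fst,
#'   size_kb), or `NULL` when the candidate holds no retained site.
#' @export
refine_boundaries <- function(candidate, sites, genome_fst, chrom_length,
                              bin = 1000, max_extension = 5e5,
                              formula = c("odds", "ratio")) {
  formula <- match.arg(formula)
  s <- sites[sites$chrom == candidate$chrom &
               (!("retained" %in% names(sites)) | sites$retained) &
               !is.na(sites$fst), , drop = FALSE]
  inside <- s$pos > candidate$start & s$pos <= candidate$end
  if (!any(inside)) return(NULL)
  peak_pos <- s$pos[inside][which.max(s$fst[inside])]
  peak_bin <- (peak_pos - 1) %/% bin

  bin_idx <- (s$pos - 1) %/% bin
  bin_mean <- tapply(s$fst, bin_idx, mean)
  b_of <- function(j) {
    m <- bin_mean[as.character(j)]
    if (is.na(m)) return(0)  # empty bin: no evidence of elevated divergence
    barrier_strength(max(m, 0), genome_fst, formula)
  }
  n_bins <- ceiling(chrom_length / bin)
  max_steps <- ceiling(max_extension / bin)

  walk <- function(step) {
    lim <- if (step > 0) min(n_bins - 1, peak_bin + max_steps) else
      max(0, peak_bin - max_steps)
    j <- peak_bin
    low_run <- 0L
    while (j != lim) {
      j <- j + step
      if (b_of(j) < 1) {
        low_run <- low_run + 1L
        if (low_run == 2L) return(j - step * 1L)  # inner edge of first low bin
      } else {
        low_run <- 0L
      }
    }
    # no stop within bounds: margin at the outermost visited bin (inclusive)
    if (low_run > 0L) j - step * (low_run - 1L) else j + step
  }
  # walk() returns, per side, the first excluded bin; region spans the bins
  # strictly between the two returned indices
  right_excl <- walk(+1L)
  left_excl <- walk(-1L)
  start <- (left_excl + 1) * bin
  end <- right_excl * bin
  start <- max(0, start)
  end <- min(end, n_bins * bin)
  if (end <= start) { start <- peak_bin * bin; end <- (peak_bin + 1) * bin }
  in_region <- s$pos > start & s$pos <= end
  data.frame(chrom = candidate$chrom, start = start, end = end,
             peak_pos = peak_pos,
             mean_fst = mean(s$fst[in_region]),
             size_kb = as.integer((end - start) / bin),
             stringsAsFactors = FALSE)
}

#' Accessibility coverage filter for divergent regions
#'
#' Keeps regions whose accessible fraction is at least `min_coverage`
#' (boundary inclusive); regions with less accessible sequence are excluded.
#'
#' @param regions data frame of regions (chrom, start, end, half-open).
#' @param mask accessible intervals (chrom, start, end; 0-based half-open),
#'   or `NULL` for fully accessible.
#' @param min_coverage minimum accessible fraction (default 0.5).
#' @return `regions` with a `coverage_fraction` column, filtered.
#' @export
coverage_filter <- function(regions, mask, min_coverage = 0.5) {
  if (!nrow(regions)) {
    regions$coverage_fraction <- double(0)
    return(regions)
  }
  acc <- window_accessible_bp(regions, mask)
  regions$coverage_fraction <- acc / (regions$end - regions$start)
  regions[regions$coverage_fraction >= min_coverage, , drop = FALSE]
}

#' Build refined divergent regions from final outlier windows
#'
#' Merges adjacent outlier windows into candidates, refines each candidate's
#' borders with the barrier-strength walk, merges refined regions that
#' overlap, and applies the accessibility coverage filter.
#'
#' @param outlier_windows data frame of final outlier windows (chrom, start,
#'   end), sorted.
#' @param sites per-site FST table ([site_fst_table()]).
#' @param genome_fst genome-wide mean per-site FST over retained sites; pass
#'   `NULL` to compute it from `sites`.
#' @param mask accessible intervals or `NULL`.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param ... passed to [refine_boundaries()].
#' @param min_coverage see [coverage_filter()].
#' @return Data frame of divergent regions (chrom, start, end, peak_pos,
#'   mean_fst, size_kb, coverage_fraction).
#' @export
build_regions <- function(outlier_windows, sites, genome_fst = NULL, mask = NULL,
                          chrom_lengths, min_coverage = 0.5, ...) {
  if (is.null(genome_fst)) {
    genome_fst <- mean(sites$fst[sites$retained], na.rm = TRUE)
  }
  cands <- merge_adjacent(outlier_windows)
  refined <- lapply(seq_len(nrow(cands)), function(i) {
    refine_boundaries(cands[i, ], sites, genome_fst,
                      chrom_lengths[[cands$chrom[i]]], ...)
  })
  refined <- do.call(rbind, Filter(Negate(is.null), refined))
  if (is.null(refined) || !nrow(refined)) {
    return(data.frame(chrom = character(), start = double(), end = double(),
                      peak_pos = double(), mean_fst = double(),
                      size_kb = integer(), coverage_fraction = double(),
                      stringsAsFactors = FALSE))
  }
  refined <- refined[order(refined$chrom, refined$start), , drop = FALSE]
  # regions are maximal by construction: merge refined regions that overlap
  new_run <- c(TRUE, !(refined$chrom[-1] == refined$chrom[-nrow(refined)] &
                         refined$start[-1] < cummax_by(refined$end, refined$chrom)[-nrow(refined)]))
  run <- cumsum(new_run)
  merged <- do.call(rbind, lapply(split(refined, run), function(g) {
    top <- g[which.max(g$mean_fst), ]
    data.frame(chrom = g$chrom[1], start = min(g$start), end = max(g$end),
               peak_pos = top$peak_pos,
               mean_fst = stats::weighted.mean(g$mean_fst, g$end - g$start),
               size_kb = as.integer((max(g$end) - min(g$start)) / 1000),
               stringsAsFactors = FALSE)
  }))
  rownames(merged) <- NULL
  coverage_filter(merged, mask, min_coverage)
}

# running maximum of x within groups (assumes rows grouped contiguously)
cummax_by <- function(x, group) {
  unsplit(lapply(split(x, factor(group, unique(group))), cummax),
          factor(group, unique(group)))
}
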
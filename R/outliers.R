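#' Flag windows above an empirical top quantile
#'
#' @param window_fst numeric vector of window FST values (`NA` = missing).
#' @param q tail fraction (default 0.01 = top 1%). Windows strictly above the
#'   `1 - q` type-7 empirical quantile of the non-missing values are flagged.
#' @return Logical vector (`FALSE` for missing windows).
#' @export
empirical_top_quantile <- function(window_fst, q = 0.01) {
  v <- window_fst[!is.na(window_fst)]
  if (!length(v)) stop("all windows are missing")
  cut <- stats::quantile(v, 1 - q, names = FALSE, type = 7)
  !is.na(window_fst) & window_fst > cut
}

#' Permutation null for window mean FST, stratified by site count
#'
#' Per-site FST values are shuffled genome-wide `n_perm` times and window
#' means recomputed each time. A window's null distribution is the pool of
#' permuted means of all windows carrying the same number of retained sites
#' (pooled across permutations); where that exact-count bin holds fewer than
#' `min_bin` draws, the nearest site count with enough draws is used. The
#' p-value uses the add-one estimator `(1 + #null >= observed) / (1 + #null)`.
#'
#' @param site_fst per-site FST values of all retained sites.
#' @param window_id integer window index (1..n_windows) of each site.
#' @param n_windows total number of windows.
#' @param n_perm number of genome-wide shuffles (>= 1000 recommended; the
#'   faithful full-scale setting is 1e6).
#' @param seed integer seed for the shuffles.
#' @param min_bin minimum null draws per site-count bin; a bin whose exact
#'   count holds fewer draws absorbs the nearest site counts (by count
#'   distance, smaller first on ties) until it reaches `min_bin`. The
#'   default 200 suits exploratory use; [scan_outliers()] raises it so the
#'   add-one p floor stays below the Benjamini-Hochberg rejection threshold.
#' @return Numeric vector of per-window p-values; `NA` for windows with no
#'   retained sites.
#' @export
permutation_null <- function(site_fst, window_id, n_windows, n_perm = 10000,
                             seed = 1L, min_bin = 200L) {
  stopifnot(length(site_fst) == length(window_id), n_perm >= 1)
  set.seed(seed)
  counts <- tabulate(window_id, nbins = n_windows)
  obs_sum <- rep(0, n_windows)
  s <- rowsum(site_fst, window_id)
  obs_sum[as.integer(rownames(s))] <- s[, 1]
  obs <- ifelse(counts > 0, obs_sum / counts, NA_real_)

  # window sums per shuffle via cumsum over window-grouped site slots; the
  # value multiset is canonicalized (sorted) first, so any site relabeling
  # preserving values and window counts yields identical p-values
  present <- sort(unique(window_id))
  ends <- cumsum(counts[present])
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  vs <- sort(site_fst)
  null_sum <- matrix(0, n_windows, n_perm)
  n_sites <- length(site_fst)
  for (b in seq_len(n_perm)) {
    cs <- c(0, cumsum(vs[sample.int(n_sites)]))
    null_sum[present, b] <- cs[ends + 1L] - cs[starts]
  }

  p <- rep(NA_real_, n_windows)
  ucounts <- sort(unique(counts[counts > 0]))
  windows_per_count <- vapply(ucounts, function(cc)
    sum(counts == cc), numeric(1))
  for (cc in ucounts) {
    wsel <- which(counts == cc)
    # absorb nearest counts until the bin holds at least min_bin draws
    use <- cc
    if (windows_per_count[match(cc, ucounts)] * n_perm < min_bin) {
      others <- ucounts[order(abs(ucounts - cc), ucounts)]
      cum <- cumsum(windows_per_count[match(others, ucounts)]) * n_perm
      use <- others[seq_len(min(which(cum >= min_bin), length(others)))]
    }
    src <- which(counts %in% use)
    null <- sort(as.vector(null_sum[src, , drop = FALSE] /
                             rep(counts[src], n_perm)))
    n_lt <- findInterval(obs[wsel], null, left.open = TRUE)
    p[wsel] <- (1 + length(null) - n_lt) / (1 + length(null))
  }
  p
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param p_values vector of p-values in (0, 1\]; `NA` allowed.
#' @param level FDR level (default 0.01).
#' @return List with `q_values` and logical `flags` (`q <= level`).
#' @export
bh_fdr <- function(p_values, level = 0.01) {
  if (!length(p_values)) stop("empty p-value vector")
  q <- stats::p.adjust(p_values, method = "BH")
  list(q_values = q, flags = !is.na(q) & q <= level)
}

#' Intersect the empirical and permutation outlier sets
#'
#' @param empirical_flags,fdr_flags logical vectors of equal length.
#' @return Logical vector: the final outlier flags (logical AND).
#' @export
final_outliers <- function(empirical_flags, fdr_flags) {
  if (length(empirical_flags) != length(fdr_flags)) {
    stop("flag vectors differ in length")
  }
  empirical_flags & fdr_flags %in% TRUE
}

#' Full outlier-window scan on a window table
#'
#' Combines the empirical top-quantile cut with the site-permutation test
#' under FDR control; the final outlier set is the intersection of the two.
#'
#' @param windows window table from [window_stats()].
#' @param sites per-site FST table from [site_fst_table()] (the `retained`
#'   sites feed the permutations).
#' @param q empirical tail fraction (default 0.01).
#' @param fdr FDR level for the permutation branch (default 0.01).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return The window table with columns `empirical_flag`, `perm_p`,
#'   `q_value`, `final_flag` appended.
#' @export
scan_outliers <- function(windows, sites, q = 0.01, fdr = 0.01,
                          n_perm = 10000, seed = 1L) {
  ws <- attr(windows, "window_size")
  stopifnot(!is.null(ws))
  ret <- sites[sites$retained & !is.na(sites$fst), , drop = FALSE]
  key <- paste(windows$chrom, windows$start %/% ws)
  wid <- match(paste(ret$chrom, (ret$pos - 1) %/% ws), key)
  windows$empirical_flag <- empirical_top_quantile(windows$fst, q)
  # the null must resolve p-values down to ~fdr * q (the BH threshold at the
  # rank where the scan's own top-quantile branch places true outliers)
  min_bin <- max(200, ceiling(10 / (fdr * q)))
  windows$perm_p <- permutation_null(ret$fst, wid, nrow(windows),
                                     n_perm = n_perm, seed = seed,
                                     min_bin = min_bin)
  bh <- bh_fdr(windows$perm_p, level = fdr)
  windows$q_value <- bh$q_values
  windows$final_flag <- final_outliers(windows$empirical_flag, bh$flags)
  windows
}
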
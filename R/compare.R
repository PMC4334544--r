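#' Permutation test for outlier windows shared between pairs
#'
#' Counts windows flagged as outliers in at least two of the supplied sets
#' and compares the count with a null in which each set's windows are placed
#' uniformly at random over the common window universe (set sizes preserved).
#'
#' @param outlier_sets list of logical vectors (one per pair) over a common
#'   window universe, or list of integer window-index vectors.
#' @param n_windows size of the window universe (required when index vectors
#'   are supplied; inferred from logical vectors otherwise).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return List with `observed_shared`, `expected_mean` (null mean),
#'   `one_tailed_p` (add-one estimator) and `null` (the permuted counts).
#' @export
shared_outlier_test <- function(outlier_sets, n_windows = NULL,
                                n_perm = 10000, seed = 1L) {
  if (length(outlier_sets) < 2) stop("need at least two outlier sets")
  if (is.logical(outlier_sets[[1]])) {
    lens <- unique(vapply(outlier_sets, length, integer(1)))
    if (length(lens) != 1) stop("outlier sets span different window universes")
    if (is.null(n_windows)) n_windows <- lens
    if (n_windows != lens) stop("outlier sets span different window universes")
    idx <- lapply(outlier_sets, which)
  } else {
    if (is.null(n_windows)) stop("n_windows required for index sets")
    if (any(unlist(outlier_sets) > n_windows)) {
      stop("outlier sets span different window universes")
    }
    idx <- outlier_sets
  }
  k <- vapply(idx, length, integer(1))
  observed <- sum(tabulate(unlist(idx), n_windows) >= 2L)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(b) {
    sum(tabulate(unlist(lapply(k, function(ki) sample.int(n_windows, ki))),
                 n_windows) >= 2L)
  }, numeric(1))
  list(observed_shared = observed, expected_mean = mean(null),
       one_tailed_p = (1 + sum(null >= observed)) / (1 + n_perm),
       null = null)
}

#' Pearson correlation of window FST between two pairs
#'
#' @param fst_a,fst_b matched window FST vectors for two population pairs.
#' @param subset `"all"` or `"outliers"`; with `"outliers"`, supply
#'   `outlier_flags` marking the windows to correlate over.
#' @param outlier_flags logical vector used when `subset = "outliers"`.
#' @return List with `r`, `p_value` and `n` complete window pairs.
#' @export
fst_correlation <- function(fst_a, fst_b, subset = c("all", "outliers"),
                            outlier_flags = NULL) {
  subset <- match.arg(subset)
  stopifnot(length(fst_a) == length(fst_b))
  keep <- !is.na(fst_a) & !is.na(fst_b)
  if (subset == "outliers") {
    stopifnot(!is.null(outlier_flags))
    keep <- keep & outlier_flags
  }
  if (sum(keep) < 3) stop("need at least 3 complete window pairs")
  ct <- stats::cor.test(fst_a[keep], fst_b[keep], method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(keep))
}

#' Mann-Whitney contrast of divergent regions against the genome
#'
#' Two-sided Mann-Whitney U test of region values against genome-wide
#' values, with a Bonferroni-adjusted significance level `alpha / n_tests`
#' for the family of per-population contrasts. Uses the exact null for small
#' untied samples and the tie-corrected normal approximation otherwise.
#'
#' @param values_in_regions,values_genomewide numeric samples (>= 2 each).
#' @param n_tests number of tests in the family (default 10: five pairs times
#'   two populations, giving threshold 0.005 at `alpha = 0.05`).
#' @param alpha family error rate (default 0.05).
#' @return List with `U` (statistic for the region sample), `p_value`,
#'   `threshold` and `significant`.
#' @export
region_vs_genome_contrast <- function(values_in_regions, values_genomewide,
                                      n_tests = 10L, alpha = 0.05) {
  x <- values_in_regions[!is.na(values_in_regions)]
  y <- values_genomewide[!is.na(values_genomewide)]
  if (length(x) < 2 || length(y) < 2) stop("both samples need >= 2 values")
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       threshold = alpha / n_tests,
       significant = wt$p.value < alpha / n_tests)
}

#' Filter and normalize a population recombination-rate map
#'
#' Drops intervals with `rho > max_rho` (highly localized breakdowns of
#' linkage disequilibrium, most likely artifacts), averages the remaining
#' interval estimates over each target window or region, and divides by the
#' population mutation rate `theta` to give the realized rho/theta measure.
#'
#' @param rho_map data frame with chrom, start, end (0-based half-open) and
#'   `rho` per interval.
#' @param theta population mutation rate normalizer (> 0).
#' @param targets data frame of windows or regions (chrom, start, end).
#' @param max_rho filter threshold on raw rho (default 100).
#' @return Numeric vector: mean filtered rho per target divided by `theta`
#'   (`NA` where no interval survives).
#' @export
rho_filter_and_normalize <- function(rho_map, theta, targets, max_rho = 100) {
  if (theta <= 0) stop("theta must be positive")
  keep <- rho_map$rho <= max_rho
  rm2 <- rho_map[keep, , drop = FALSE]
  out <- rep(NA_real_, nrow(targets))
  if (!nrow(rm2)) return(out)
  q <- GenomicRanges::GRanges(targets$chrom,
                              IRanges::IRanges(targets$start + 1, targets$end))
  s <- GenomicRanges::GRanges(rm2$chrom,
                              IRanges::IRanges(rm2$start + 1, rm2$end))
  hits <- GenomicRanges::findOverlaps(q, s)
  means <- tapply(rm2$rho[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), mean)
  out[as.integer(names(means))] <- as.double(means) / theta
  out
}

#' Shannon diversity of parasite loads per fish
#'
#' Parasite counts are 4th-root transformed before computing
#' `H = -sum(p_i * log(p_i))` over taxa with positive transformed abundance.
#' A fish without any parasite gets `H = 0` by convention.
#'
#' @param counts matrix or data frame, fish (rows) x parasite taxa (columns),
#'   non-negative counts.
#' @return Numeric vector: H per fish (natural log).
#' @export
shannon_diversity <- function(counts) {
  m <- as.matrix(counts)
  if (any(m < 0)) stop("parasite counts must be non-negative")
  m <- m^(1 / 4)
  apply(m, 1, function(x) {
    s <- sum(x)
    if (s == 0) return(0)
    p <- x[x > 0] / s
    -sum(p * log(p))
  })
}

#' Quantitative Jaccard (Ruzicka) distance between parasite communities
#'
#' Parasite counts are summed over individuals within each population and
#' 4th-root transformed; the pairwise distance is
#' `1 - sum(min(a, b)) / sum(max(a, b))`. Set `binary = TRUE` for classic
#' presence/absence Jaccard.
#'
#' @param counts_by_pop matrix or data frame, populations (rows) x taxa
#'   (columns), of summed counts; or a list of per-fish count matrices that
#'   are summed here.
#' @param binary use presence/absence Jaccard instead (default `FALSE`).
#' @return A symmetric distance matrix with zero diagonal.
#' @export
community_distance <- function(counts_by_pop, binary = FALSE) {
  if (is.list(counts_by_pop) && !is.data.frame(counts_by_pop)) {
    counts_by_pop <- t(vapply(counts_by_pop, colSums,
                              numeric(ncol(counts_by_pop[[1]]))))
  }
  m <- as.matrix(counts_by_pop)^(1 / 4)
  if (binary) m <- (m > 0) * 1
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      mx <- sum(pmax(m[i, ], m[j, ]))
      d[i, j] <- d[j, i] <- if (mx == 0) 0 else
        1 - sum(pmin(m[i, ], m[j, ])) / mx
    }
  }
  d
}

#' Great-circle distance between GPS coordinates
#'
#' Haversine distance on a sphere of radius 6371.0088 km.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorized).
#' @return Distance in km.
#' @export
geodetic_distance <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180)) {
    stop("coordinates out of range")
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371008.8) / 1000
}

#' Distance matrix of great-circle distances between sampling sites
#'
#' @param gps data frame with columns `population`, `lat`, `lon`.
#' @return Symmetric km distance matrix.
#' @export
gps_distance_matrix <- function(gps) {
  n <- nrow(gps)
  d <- matrix(0, n, n, dimnames = list(gps$population, gps$population))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      d[i, j] <- d[j, i] <- geodetic_distance(gps$lat[i], gps$lon[i],
                                              gps$lat[j], gps$lon[j])
    }
  }
  d
}

#' Partial Mantel test (isolation by adaptation)
#'
#' Partial Pearson correlation between the genetic and ecological distance
#' matrices controlling for geographic distance, with significance assessed
#' by permuting the row/column labels of the genetic matrix. All label
#' permutations are enumerated exactly when the matrices have at most
#' `exact_max` populations; otherwise `n_perm` random permutations are drawn
#' and the add-one p-value estimator is used. One-tailed (positive
#' association) by default.
#'
#' @param genetic,ecological,geographic square symmetric distance matrices
#'   with zero diagonals and identical label order.
#' @param n_perm random permutations when not enumerating (default 9999).
#' @param seed integer seed (sampled mode).
#' @param exact_max enumerate all permutations up to this matrix size
#'   (default 8).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return List with `r`, `p_value`, `n_perm_used` and `exact`.
#' @export
partial_mantel <- function(genetic, ecological, geographic, n_perm = 9999,
                           seed = 1L, exact_max = 8L,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- nrow(genetic)
  check_dist <- function(m, nm) {
    if (!isTRUE(all.equal(m, t(m))) || any(diag(m) != 0) ||
        nrow(m) != n || ncol(m) != n) {
      stop(nm, " must be a square symmetric zero-diagonal matrix of matching size")
    }
  }
  check_dist(genetic, "genetic"); check_dist(ecological, "ecological")
  check_dist(geographic, "geographic")
  if (n < 4) stop("need at least 4 populations")
  low <- lower.tri(genetic)
  partial_r <- function(g) {
    x <- g[low]; y <- ecological[low]; z <- geographic[low]
    rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
    (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  }
  r_obs <- partial_r(genetic)
  tail_stat <- function(r) if (alternative == "greater") r else abs(r)
  if (n <= exact_max) {
    perms <- permutations_of(n)
    stat <- vapply(seq_len(nrow(perms)), function(i) {
      p <- perms[i, ]
      tail_stat(partial_r(genetic[p, p]))
    }, numeric(1))
    p_value <- sum(stat >= tail_stat(r_obs) - 1e-12) / nrow(perms)
    list(r = r_obs, p_value = p_value, n_perm_used = nrow(perms), exact = TRUE)
  } else {
    set.seed(seed)
    stat <- vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      tail_stat(partial_r(genetic[p, p]))
    }, numeric(1))
    p_value <- (1 + sum(stat >= tail_stat(r_obs) - 1e-12)) / (1 + n_perm)
    list(r = r_obs, p_value = p_value, n_perm_used = n_perm, exact = FALSE)
  }
}

# all permutations of 1..n (n! rows); recursion is fine for n <= 8
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
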
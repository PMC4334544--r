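#' Per-site Weir-Cockerham FST for two populations
#'
#' Variance-components estimator (theta-hat) of Weir & Cockerham (1984) for
#' haplotype allele counts from two populations. Values can be negative for
#' weakly differentiated sites; sites monomorphic across the pooled pair are
#' returned as `NA`.
#'
#' @param ac1,ac2 alternate-allele counts per site in population 1 and 2.
#' @param n1,n2 number of called alleles per site (scalar or vector).
#' @return Numeric vector of per-site FST estimates.
#' @export
site_fst_wc <- function(ac1, n1, ac2, n2) {
  k <- max(length(ac1), length(ac2))
  n1 <- rep_len(n1, k); n2 <- rep_len(n2, k)
  if (any(n1 < 2 | n2 < 2)) stop("need at least 2 called alleles per population")
  p1 <- ac1 / n1; p2 <- ac2 / n2
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r) / (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - s2 * (r - 1) / r)
  th <- a / (a + b)
  th[pbar <= 0 | pbar >= 1] <- NA_real_
  th
}

#' Pooled minor-allele-frequency filter for the FST scan
#'
#' Retains sites whose minor-allele frequency across the pooled pair is at
#' least `threshold`, removing weakly informative polymorphism from the scan
#' input. The filter applies to FST only; diversity statistics (pi, theta,
#' Tajima's D, Dxy) use all sites.
#'
#' @param ac1,n1,ac2,n2 per-site allele counts and called-allele numbers.
#' @param threshold minimum pooled minor-allele frequency, in \[0, 0.5\].
#' @return Logical vector: `TRUE` for retained sites.
#' @export
maf_filter_pair <- function(ac1, n1, ac2, n2, threshold = 0.25) {
  if (threshold < 0 || threshold > 0.5) stop("threshold must be in [0, 0.5]")
  ac <- ac1 + ac2
  an <- rep_len(n1, length(ac)) + rep_len(n2, length(ac))
  pmin(ac, an - ac) / an >= threshold
}

# Tajima (1989) constants for a sample of n sequences
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D from per-site allele counts
#'
#' Computes D from the number of segregating sites and the mean number of
#' pairwise differences implied by the allele counts. Returns `NA` when fewer
#' than `min_s` sites segregate (unstable denominator).
#'
#' @param ac alternate-allele counts per site.
#' @param an called alleles per site.
#' @param min_s minimum number of segregating sites (default 3).
#' @return Scalar Tajima's D, or `NA`.
#' @export
tajimas_d <- function(ac, an, min_s = 3L) {
  seg <- ac > 0 & ac < an
  ac <- ac[seg]; an <- an[seg]
  s <- length(ac)
  if (s < min_s) return(NA_real_)
  n <- round(mean(an))
  if (n < 4) return(NA_real_)
  k <- tajima_constants(n)
  pi_sum <- sum(2 * ac * (an - ac) / (an * (an - 1)))
  (pi_sum - s / k$a1) / sqrt(k$e1 * s + k$e2 * s * (s - 1))
}

# all per-site quantities used by window aggregation, as a data frame
site_components <- function(pop1, pop2, maf_threshold = 0.25) {
  stopifnot(identical(pop1$chrom, pop2$chrom), identical(pop1$pos, pop2$pos))
  c1 <- allele_counts(pop1); c2 <- allele_counts(pop2)
  ok <- c1$an >= 2 & c2$an >= 2
  fst <- rep(NA_real_, length(c1$ac))
  fst[ok] <- site_fst_wc(c1$ac[ok], c1$an[ok], c2$ac[ok], c2$an[ok])
  p1 <- c1$ac / c1$an; p2 <- c2$ac / c2$an
  data.frame(chrom = pop1$chrom, pos = pop1$pos,
             ac1 = c1$ac, an1 = c1$an, ac2 = c2$ac, an2 = c2$an,
             fst = fst,
             retained = ok & !is.na(fst) &
               maf_filter_pair(c1$ac, c1$an, c2$ac, c2$an, maf_threshold),
             dxy = p1 * (1 - p2) + p2 * (1 - p1),
             het1 = ifelse(c1$an > 1, 2 * c1$ac * (c1$an - c1$ac) /
                             (c1$an * (c1$an - 1)), NA_real_),
             het2 = ifelse(c2$an > 1, 2 * c2$ac * (c2$an - c2$ac) /
                             (c2$an * (c2$an - 1)), NA_real_),
             seg1 = c1$ac > 0 & c1$ac < c1$an,
             seg2 = c2$ac > 0 & c2$ac < c2$an,
             stringsAsFactors = FALSE)
}

#' Per-site FST table for a population pair
#'
#' @param pop1,pop2 [genotype_matrix()] objects over identical loci.
#' @param maf_threshold pooled minor-allele-frequency threshold marking sites
#'   retained for the FST scan.
#' @return Data frame with chrom, pos, fst and a logical `retained` column.
#' @export
site_fst_table <- function(pop1, pop2, maf_threshold = 0.25) {
  sc <- site_components(pop1, pop2, maf_threshold)
  sc[, c("chrom", "pos", "fst", "retained")]
}

# tile [0, len) into half-open windows of the given size, per chromosome
tile_windows <- function(chrom_lengths, window_size) {
  out <- lapply(names(chrom_lengths), function(ch) {
    n <- ceiling(chrom_lengths[[ch]] / window_size)
    data.frame(chrom = ch, start = (seq_len(n) - 1) * window_size,
               end = pmin(seq_len(n) * window_size, chrom_lengths[[ch]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# accessible bp of each half-open window under the mask (NULL = all accessible)
window_accessible_bp <- function(windows, mask) {
  if (is.null(mask)) return(windows$end - windows$start)
  q <- GenomicRanges::GRanges(windows$chrom,
                              IRanges::IRanges(windows$start + 1, windows$end))
  s <- GenomicRanges::reduce(GenomicRanges::GRanges(
    mask$chrom, IRanges::IRanges(mask$start + 1, mask$end)))
  hits <- GenomicRanges::findOverlaps(q, s)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(q)[S4Vectors::queryHits(hits)],
    IRanges::ranges(s)[S4Vectors::subjectHits(hits)]))
  acc <- rep(0, nrow(windows))
  tot <- tapply(ov, S4Vectors::queryHits(hits), sum)
  acc[as.integer(names(tot))] <- as.double(tot)
  acc
}

#' Windowed population-genetic statistics for a population pair
#'
#' Tiles each chromosome into non-overlapping half-open windows and reports,
#' per window: the number of pooled segregating sites, accessible bp under the
#' mask, mean per-site Weir-Cockerham FST over MAF-retained sites, nucleotide
#' diversity pi and Watterson's theta per population (per accessible bp),
#' Tajima's D per population, and absolute divergence Dxy (per accessible bp).
#' Statistics are `NA` (not zero) where no data exist: FST without retained
#' sites, all statistics without accessible bp, Tajima's D with fewer than 3
#' segregating sites.
#'
#' @param pop1,pop2 [genotype_matrix()] objects over identical loci.
#' @param mask accessible intervals (data frame chrom, start, end; 0-based
#'   half-open), or `NULL` for fully accessible.
#' @param window_size window size in bp (default 10000).
#' @param chrom_lengths named vector of chromosome lengths; defaults to the
#'   last window end implied by the data.
#' @param maf_threshold pooled MAF threshold for the FST scan input.
#' @return Data frame with one row per window, plus attributes `n1`, `n2`
#'   (haplotype panel sizes) and `window_size`.
#' @export
window_stats <- function(pop1, pop2, mask = NULL, window_size = 10000,
                         chrom_lengths = NULL, maf_threshold = 0.25) {
  sc <- site_components(pop1, pop2, maf_threshold)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(sc$pos, sc$chrom, max)
    chrom_lengths <- ceiling(chrom_lengths / window_size) * window_size
    chrom_lengths <- stats::setNames(as.double(chrom_lengths),
                                     names(chrom_lengths))
  }
  w <- tile_windows(chrom_lengths, window_size)
  w$n_accessible_bp <- window_accessible_bp(w, mask)
  key <- paste(w$chrom, w$start %/% window_size)
  wid <- match(paste(sc$chrom, (sc$pos - 1) %/% window_size), key)
  if (anyNA(wid)) stop("sites outside the provided chromosome lengths")

  agg <- function(x, sel = TRUE) {
    v <- rep(0, nrow(w))
    if (!length(x) || !sum(sel)) return(v)
    s <- rowsum(as.double(x[sel]), wid[sel])
    v[as.integer(rownames(s))] <- s[, 1]
    v
  }
  seg_pool <- (sc$ac1 + sc$ac2) > 0 & (sc$ac1 + sc$ac2) < (sc$an1 + sc$an2)
  w$n_snps <- agg(as.double(seg_pool))
  w$n_sites_fst <- agg(as.double(sc$retained))
  fst_sum <- agg(ifelse(sc$retained, sc$fst, 0))
  w$fst <- ifelse(w$n_sites_fst > 0, fst_sum / w$n_sites_fst, NA_real_)

  n1 <- n_haplotypes(pop1); n2 <- n_haplotypes(pop2)
  s1 <- agg(as.double(sc$seg1)); s2 <- agg(as.double(sc$seg2))
  pi1 <- agg(ifelse(sc$seg1, sc$het1, 0)); pi2 <- agg(ifelse(sc$seg2, sc$het2, 0))
  acc <- w$n_accessible_bp
  w$pi_pop1 <- ifelse(acc > 0, pi1 / acc, NA_real_)
  w$pi_pop2 <- ifelse(acc > 0, pi2 / acc, NA_real_)
  w$theta_pop1 <- ifelse(acc > 0, s1 / tajima_constants(n1)$a1 / acc, NA_real_)
  w$theta_pop2 <- ifelse(acc > 0, s2 / tajima_constants(n2)$a1 / acc, NA_real_)
  w$dxy <- ifelse(acc > 0, agg(sc$dxy) / acc, NA_real_)

  td_of <- function(s, pi_sum, n) {
    k <- tajima_constants(n)
    ifelse(s >= 3 & acc > 0,
           (pi_sum - s / k$a1) / sqrt(k$e1 * s + k$e2 * s * (s - 1)),
           NA_real_)
  }
  w$td_pop1 <- td_of(s1, pi1, n1)
  w$td_pop2 <- td_of(s2, pi2, n2)
  w[acc == 0, c("fst", "pi_pop1", "pi_pop2", "theta_pop1", "theta_pop2",
                "dxy", "td_pop1", "td_pop2")] <- NA_real_
  attr(w, "n1") <- n1; attr(w, "n2") <- n2
  attr(w, "window_size") <- window_size
  w
}

#' Jackknife uncertainty of a window FST estimate
#'
#' Recomputes the window mean of per-site Weir-Cockerham FST over every
#' combination of leaving one diploid individual out of each population, and
#' reports the jackknife mean and the width of the central 95% interval of
#' the leave-one-out estimates.
#'
#' @param pop1,pop2 [genotype_matrix()] objects restricted to the window's
#'   sites (identical loci). Individuals are consecutive haplotype pairs.
#' @param maf_threshold pooled MAF threshold applied within each leave-one-out
#'   replicate.
#' @return List with `mean`, `ci_width` and the vector of `estimates`;
#'   `NA` mean if every replicate is monomorphic.
#' @export
jackknife_window_fst <- function(pop1, pop2, maf_threshold = 0.25) {
  k1 <- ncol(pop1$haps) / 2; k2 <- ncol(pop2$haps) / 2
  if (k1 < 3 || k2 < 3) stop("need at least 3 individuals per population")
  one <- function(h, drop_ind) h[, -c(2 * drop_ind - 1, 2 * drop_ind), drop = FALSE]
  est <- matrix(NA_real_, k1, k2)
  for (i in seq_len(k1)) {
    h1 <- one(pop1$haps, i)
    for (j in seq_len(k2)) {
      h2 <- one(pop2$haps, j)
      ac1 <- rowSums(h1 == 1L, na.rm = TRUE); an1 <- rowSums(!is.na(h1))
      ac2 <- rowSums(h2 == 1L, na.rm = TRUE); an2 <- rowSums(!is.na(h2))
      ok <- an1 >= 2 & an2 >= 2
      if (!any(ok)) next
      fst <- site_fst_wc(ac1[ok], an1[ok], ac2[ok], an2[ok])
      keep <- !is.na(fst) &
        maf_filter_pair(ac1[ok], an1[ok], ac2[ok], an2[ok], maf_threshold)
      if (any(keep)) est[i, j] <- mean(fst[keep])
    }
  }
  v <- est[!is.na(est)]
  if (!length(v)) {
    return(list(mean = NA_real_, ci_width = NA_real_, estimates = est))
  }
  qs <- stats::quantile(v, c(0.025, 0.975), names = FALSE, type = 7)
  list(mean = mean(v), ci_width = qs[2] - qs[1], estimates = est)
}
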
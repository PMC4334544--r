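test_that("site FST handles fixed differences, no differentiation, and errors", {
  expect_equal(site_fst_wc(12, 12, 0, 12), 1)
  expect_lte(site_fst_wc(6, 12, 6, 12), 0)
  expect_error(site_fst_wc(0, 0, 3, 12), "at least 2")
  # monomorphic across the pooled pair is undefined
  expect_true(is.na(site_fst_wc(0, 12, 0, 12)))
  expect_true(is.na(site_fst_wc(12, 12, 12, 12)))
})

test_that("site FST matches the mean-square oracle and is symmetric", {
  set.seed(42)
  for (i in 1:200) {
    n1 <- sample(4:20, 1); n2 <- sample(4:20, 1)
    ac1 <- sample(0:n1, 1); ac2 <- sample(0:n2, 1)
    if (ac1 + ac2 == 0 || ac1 + ac2 == n1 + n2) next
    impl <- site_fst_wc(ac1, n1, ac2, n2)
    expect_equal(impl, oracle_wc_fst(ac1, n1, ac2, n2), tolerance = 1e-12)
    # population symmetry and allele-label swap invariance
    expect_equal(impl, site_fst_wc(ac2, n2, ac1, n1), tolerance = 1e-12)
    expect_equal(impl, site_fst_wc(n1 - ac1, n1, n2 - ac2, n2),
                 tolerance = 1e-12)
  }
})

test_that("MAF filter retains by pooled minor-allele frequency", {
  # pooled MAF 0.30 kept, 0.10 removed
  expect_true(maf_filter_pair(3, 10, 3, 10))
  flags <- maf_filter_pair(c(7, 2), c(12, 12), c(0, 0), c(12, 12))
  expect_equal(flags, c(TRUE, FALSE))
  expect_error(maf_filter_pair(1, 12, 1, 12, threshold = 0.6), "threshold")
  # retained fraction equals direct enumeration on simulated counts
  set.seed(1)
  ac1 <- sample(0:12, 1000, replace = TRUE)
  ac2 <- sample(0:12, 1000, replace = TRUE)
  maf <- pmin(ac1 + ac2, 24 - ac1 - ac2) / 24
  expect_equal(maf_filter_pair(ac1, 12, ac2, 12), maf >= 0.25)
})

test_that("windowed estimators agree with brute-force oracles", {
  set.seed(7)
  for (i in 1:60) {
    rp <- random_pair(n_sites = sample(10:50, 1))
    w <- window_stats(rp$pop1, rp$pop2, mask = NULL, window_size = rp$len,
                      chrom_lengths = c(chr1 = rp$len))
    expect_equal(nrow(w), 1L)
    expect_equal(w$pi_pop1, oracle_pi(rp$pop1$haps, rp$len), tolerance = 1e-10)
    expect_equal(w$pi_pop2, oracle_pi(rp$pop2$haps, rp$len), tolerance = 1e-10)
    expect_equal(w$theta_pop1, oracle_theta_w(rp$pop1$haps, rp$len),
                 tolerance = 1e-10)
    expect_equal(w$dxy, oracle_dxy(rp$pop1$haps, rp$pop2$haps, rp$len),
                 tolerance = 1e-10)
    td <- oracle_tajima_d(rp$pop1$haps)
    if (is.na(td)) expect_true(is.na(w$td_pop1)) else
      expect_equal(w$td_pop1, td, tolerance = 1e-10)
  }
})

test_that("window statistics honor missingness conventions", {
  # no SNPs but accessible sequence: pi = 0, Tajima's D missing
  empty1 <- genotype_matrix(character(0), integer(0),
                            matrix(0L, 0, 12))
  empty2 <- genotype_matrix(character(0), integer(0),
                            matrix(0L, 0, 12))
  w <- window_stats(empty1, empty2, mask = NULL, window_size = 1e4,
                    chrom_lengths = c(chr1 = 1e4))
  expect_equal(w$pi_pop1, 0)
  expect_true(is.na(w$td_pop1))
  expect_true(is.na(w$fst))

  # one fixed difference in 10 kb accessible: Dxy = 1/10000
  one1 <- genotype_matrix("chr1", 500L, matrix(1L, 1, 12))
  one2 <- genotype_matrix("chr1", 500L, matrix(0L, 1, 12))
  w1 <- window_stats(one1, one2, mask = NULL, window_size = 1e4,
                     chrom_lengths = c(chr1 = 1e4))
  expect_equal(w1$dxy, 1 / 10000)
  expect_equal(w1$fst, 1)

  # zero accessible bp: all statistics missing
  m <- data.frame(chrom = "chr1", start = 10000, end = 20000)
  w2 <- window_stats(one1, one2, mask = m, window_size = 1e4,
                     chrom_lengths = c(chr1 = 2e4))
  expect_true(all(is.na(
    w2[1, c("fst", "pi_pop1", "dxy", "td_pop1", "theta_pop2")])))
})

test_that("Tajima's D matches the published-formula oracle on a constructed matrix", {
  set.seed(11)
  # n = 10 haplotypes, fixed number of segregating sites
  h <- matrix(0L, 16, 10)
  for (i in 1:16) h[i, sample.int(10, sample(1:9, 1))] <- 1L
  gm <- genotype_matrix(rep("chr1", 16), sort(sample.int(9000, 16)), h)
  cc <- allele_counts(gm)
  expect_equal(tajimas_d(cc$ac, cc$an), oracle_tajima_d(h), tolerance = 1e-10)
  # fewer than 3 segregating sites is undefined
  expect_true(is.na(tajimas_d(c(3, 5), c(10, 10))))
})

test_that("window means are invariant to site order and keep negative FST", {
  set.seed(3)
  rp <- random_pair(n_sites = 40)
  w <- window_stats(rp$pop1, rp$pop2, NULL, rp$len, c(chr1 = rp$len))
  # feed sites in scrambled order; genotype_matrix re-sorts them
  idx <- sample(length(rp$pop1$pos))
  p1 <- genotype_matrix(rp$pop1$chrom[idx], rp$pop1$pos[idx],
                        rp$pop1$haps[idx, ])
  p2 <- genotype_matrix(rp$pop2$chrom[idx], rp$pop2$pos[idx],
                        rp$pop2$haps[idx, ])
  w2 <- window_stats(p1, p2, NULL, rp$len, c(chr1 = rp$len))
  expect_equal(w, w2)
  # negative per-site estimates are averaged, not clamped
  s <- site_fst_table(rp$pop1, rp$pop2, maf_threshold = 0)
  if (any(s$fst < 0, na.rm = TRUE)) {
    expect_lt(min(s$fst, na.rm = TRUE), 0)
  }
})

test_that("jackknife FST enumerates all leave-one-out pairs", {
  set.seed(5)
  rp <- random_pair(n_sites = 25)
  jk <- jackknife_window_fst(rp$pop1, rp$pop2)
  expect_equal(dim(jk$estimates), c(6, 6))
  # explicit enumeration with independent allele-count arithmetic
  manual <- matrix(NA_real_, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    h1 <- rp$pop1$haps[, -c(2 * i - 1, 2 * i)]
    h2 <- rp$pop2$haps[, -c(2 * j - 1, 2 * j)]
    vals <- c()
    for (s in seq_len(nrow(h1))) {
      ac1 <- sum(h1[s, ]); ac2 <- sum(h2[s, ])
      if (pmin(ac1 + ac2, 20 - ac1 - ac2) / 20 < 0.25) next
      v <- oracle_wc_fst(ac1, 10, ac2, 10)
      if (!is.na(v)) vals <- c(vals, v)
    }
    if (length(vals)) manual[i, j] <- mean(vals)
  }
  expect_equal(jk$estimates, manual, tolerance = 1e-12)
  expect_equal(jk$mean, mean(manual[!is.na(manual)]), tolerance = 1e-12)

  # identical individuals within each population: zero resampling variance
  same1 <- genotype_matrix(c("chr1", "chr1"), c(100L, 200L),
                           matrix(1L, 2, 12))
  same2 <- genotype_matrix(c("chr1", "chr1"), c(100L, 200L),
                           matrix(rep(c(0L, 1L), each = 1, times = 12), 2, 12))
  jk2 <- jackknife_window_fst(same1, same2)
  expect_equal(jk2$ci_width, 0)

  # monomorphic window is missing
  mono1 <- genotype_matrix("chr1", 100L, matrix(1L, 1, 12))
  mono2 <- genotype_matrix("chr1", 100L, matrix(1L, 1, 12))
  expect_true(is.na(jackknife_window_fst(mono1, mono2)$mean))

  expect_error(jackknife_window_fst(
    genotype_matrix("chr1", 1L, matrix(0:1, 1, 4)),
    genotype_matrix("chr1", 1L, matrix(0:1, 1, 4))), "3 individuals")
})
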
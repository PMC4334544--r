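test_that("shared-outlier permutation behaves at the edges and matches expectation", {
  a <- c(rep(TRUE, 10), rep(FALSE, 90))
  r_same <- shared_outlier_test(list(a, a), n_perm = 200, seed = 1)
  expect_equal(r_same$observed_shared, 10)
  expect_lt(r_same$one_tailed_p, 0.05)

  b <- c(rep(FALSE, 90), rep(TRUE, 10))
  big_a <- c(rep(TRUE, 10), rep(FALSE, 4990))
  big_b <- c(rep(FALSE, 4990), rep(TRUE, 10))
  r_disj <- shared_outlier_test(list(big_a, big_b), n_perm = 200, seed = 2)
  expect_equal(r_disj$observed_shared, 0)
  expect_gt(r_disj$one_tailed_p, 0.9)

  # permutation mean approaches the hypergeometric expectation k1*k2/N
  r <- shared_outlier_test(list(a, b), n_perm = 5000, seed = 3)
  expect_lt(abs(r$expected_mean - 1), 0.08)

  expect_error(shared_outlier_test(list(a, c(a, FALSE))), "universes")
  expect_error(shared_outlier_test(list(a)), "two")
})

test_that("FST correlations recover exact and hand-computed values", {
  x <- c(0.1, 0.3, 0.5, 0.7, 0.2)
  expect_equal(fst_correlation(x, x)$r, 1)
  expect_equal(fst_correlation(x, -x)$r, -1)
  set.seed(5)
  a <- runif(20); b <- runif(20)
  r <- fst_correlation(a, b)$r
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(r, manual, tolerance = 1e-12)
  expect_error(fst_correlation(c(1, 2), c(1, 2)), "3")
  # outlier subset restricts the windows used
  fl <- c(rep(TRUE, 10), rep(FALSE, 10))
  r_out <- fst_correlation(a, b, subset = "outliers", outlier_flags = fl)
  expect_equal(r_out$n, 10)
})

test_that("Mann-Whitney contrast matches exact enumeration and the threshold rule", {
  set.seed(11)
  for (i in 1:10) {
    x <- round(rnorm(sample(4:7, 1)), 2)
    y <- round(rnorm(sample(4:7, 1)), 2)
    if (anyDuplicated(c(x, y))) next  # enumeration oracle assumes no ties
    got <- region_vs_genome_contrast(x, y)
    expect_equal(got$p_value, oracle_mann_whitney(x, y), tolerance = 1e-9)
  }
  # identical samples: p = 1
  z <- 1:10 / 10
  expect_equal(region_vs_genome_contrast(z, z)$p_value, 1)
  # complete separation at n = 20 each: U = 0 and significant at 0.005
  lowx <- seq(0.01, 0.2, length.out = 20)
  highy <- seq(1, 2, length.out = 20)
  r <- region_vs_genome_contrast(lowx, highy, n_tests = 10)
  expect_equal(unname(r$U), 0)
  expect_lt(r$p_value, 0.005)
  expect_equal(r$threshold, 0.005)
  expect_true(r$significant)
  expect_error(region_vs_genome_contrast(numeric(0), z), "2 values")
})

test_that("recombination map filtering averages surviving intervals per target", {
  rho <- data.frame(chrom = "chr1", start = c(0, 100, 200), end = c(100, 200, 300),
                    rho = c(5, 150, 7))
  target <- data.frame(chrom = "chr1", start = 0, end = 300)
  expect_equal(rho_filter_and_normalize(rho, 1, target), 6)
  expect_equal(rho_filter_and_normalize(rho, 0.01, target), 600)
  # all intervals filtered: missing
  rho_hi <- transform(rho, rho = rho + 1000)
  expect_true(is.na(rho_filter_and_normalize(rho_hi, 1, target)))
  expect_error(rho_filter_and_normalize(rho, 0, target), "theta")
})

test_that("Shannon diversity applies the 4th-root transform", {
  expect_equal(shannon_diversity(matrix(c(16, 16, 16, 16), 1)), log(4))
  expect_equal(shannon_diversity(matrix(c(81, 0, 0), 1)), 0)
  h <- shannon_diversity(matrix(c(16, 1), 1))
  expect_equal(h, -(2 / 3) * log(2 / 3) - (1 / 3) * log(1 / 3))
  expect_equal(shannon_diversity(matrix(0, 1, 3)), 0)
  expect_error(shannon_diversity(matrix(-1, 1, 1)), "non-negative")
})

test_that("community distance is Ruzicka on transformed counts", {
  same <- rbind(a = c(16, 1, 0), b = c(16, 1, 0))
  expect_equal(community_distance(same)["a", "b"], 0)
  disjoint <- rbind(a = c(5, 0), b = c(0, 7))
  expect_equal(community_distance(disjoint)[1, 2], 1)
  toy <- rbind(a = c(16, 0), b = c(1, 1))  # transformed: (2,0) vs (1,1)
  expect_equal(community_distance(toy)[1, 2], 1 - 1 / 3)
  # symmetry, zero diagonal, non-negativity
  set.seed(2)
  m <- matrix(rpois(20, 4), 4, 5)
  d <- community_distance(m)
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, 4))
  expect_true(all(d >= 0))
  # binary mode reduces to presence/absence Jaccard
  expect_equal(community_distance(toy, binary = TRUE)[1, 2], 1 / 2)
})

test_that("geodetic distances follow the haversine formula", {
  expect_equal(geodetic_distance(10, 20, 10, 20), 0)
  expect_equal(geodetic_distance(0, 0, 0, 180), pi * 6371.0088,
               tolerance = 1e-6)
  expect_equal(geodetic_distance(0, 0, 1, 0), 2 * pi * 6371.0088 / 360,
               tolerance = 1e-6)
  expect_error(geodetic_distance(95, 0, 0, 0), "range")
  gps <- data.frame(population = c("a", "b", "c"),
                    lat = c(54, 54.5, 55), lon = c(10, 10.2, 10.4))
  d <- gps_distance_matrix(gps)
  expect_equal(d, t(d))
  expect_equal(diag(d), setNames(rep(0, 3), gps$population))
})

test_that("partial Mantel recovers a planted association and is deterministic", {
  set.seed(17)
  n <- 7
  sym <- function(m) { m <- abs(m + t(m)) / 2; diag(m) <- 0; m }
  g <- sym(matrix(rnorm(n * n), n))
  geo <- sym(matrix(rnorm(n * n), n))
  r_ident <- partial_mantel(g, g + sym(matrix(rnorm(n * n, 0, 1e-3), n)), geo)
  expect_gt(r_ident$r, 0.99)
  expect_true(r_ident$exact)
  expect_lt(r_ident$p_value, 0.01)

  # sampled mode is seed-deterministic
  n2 <- 10
  g2 <- sym(matrix(rnorm(n2 * n2), n2))
  e2 <- sym(matrix(rnorm(n2 * n2), n2))
  x2 <- sym(matrix(rnorm(n2 * n2), n2))
  p_a <- partial_mantel(g2, e2, x2, n_perm = 99, seed = 4)
  p_b <- partial_mantel(g2, e2, x2, n_perm = 99, seed = 4)
  expect_identical(p_a, p_b)
  expect_false(p_a$exact)

  expect_error(partial_mantel(g[1:3, 1:3], g[1:3, 1:3], g[1:3, 1:3]), "4")
  asym <- g; asym[1, 2] <- 99
  expect_error(partial_mantel(asym, g, geo), "symmetric")
})

test_that("partial Mantel r agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(23)
  n <- 8
  sym <- function(m) { m <- abs(m + t(m)) / 2; diag(m) <- 0; m }
  g <- sym(matrix(rnorm(n * n), n)); e <- sym(matrix(rnorm(n * n), n))
  x <- sym(matrix(rnorm(n * n), n))
  ours <- partial_mantel(g, e, x)
  ref <- vegan::mantel.partial(as.dist(g), as.dist(e), as.dist(x),
                               permutations = 99)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-10)
})
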
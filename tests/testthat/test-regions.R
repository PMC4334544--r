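test_that("adjacent outlier windows merge, gaps break runs", {
  w <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                  start = c(10000, 20000, 40000, 20000),
                  end = c(20000, 30000, 50000, 30000))
  m <- merge_adjacent(w)
  expect_equal(nrow(m), 3L)
  expect_equal(m$start, c(10000, 40000, 20000))
  expect_equal(m$end, c(30000, 50000, 30000))

  expect_equal(nrow(merge_adjacent(w[0, ])), 0L)
  expect_error(merge_adjacent(w[c(2, 1), ]), "sorted")
  # merging never increases the count
  expect_lte(nrow(m), nrow(w))
})

test_that("barrier strength follows the effective-migration odds ratio", {
  expect_equal(barrier_strength(0.2, 0.2), 1)
  expect_equal(barrier_strength(0, 0.3), 0)
  expect_equal(barrier_strength(0.5, 0.2), 4)  # (1)/(0.25)
  expect_equal(barrier_strength(1, 0.2), Inf)
  expect_error(barrier_strength(0.5, 0), "genome_fst")
  # plain-ratio variant
  expect_equal(barrier_strength(0.4, 0.2, formula = "ratio"), 2)
})

# a deterministic step-function site profile: high FST inside a block,
# background level outside, sites every 100 bp
step_profile <- function(block_start = 40000, block_end = 50000,
                         len = 100000, high = 0.6, low = 0.1) {
  pos <- seq(50, len - 50, by = 100)
  fst <- ifelse(pos > block_start & pos <= block_end, high, low)
  data.frame(chrom = "chr1", pos = pos, fst = fst, retained = TRUE)
}

test_that("boundary refinement recovers a step-function block to 1 kb", {
  sites <- step_profile()
  genome_fst <- mean(sites$fst)  # elevated above the outside level
  cand <- data.frame(chrom = "chr1", start = 40000, end = 50000)
  r1 <- refine_boundaries(cand, sites, genome_fst, chrom_length = 100000)
  expect_lte(abs(r1$start - 40000), 1000)
  expect_lte(abs(r1$end - 50000), 1000)
  expect_true(r1$peak_pos > r1$start & r1$peak_pos <= r1$end)
  # peak ties break leftmost
  expect_equal(r1$peak_pos, min(sites$pos[sites$fst == 0.6]))
  # exact reproducibility
  r2 <- refine_boundaries(cand, sites, genome_fst, chrom_length = 100000)
  expect_identical(r1, r2)
})

test_that("a flat profile at the genome-wide level walks to the cap", {
  sites <- step_profile(high = 0.2, low = 0.2)
  cand <- data.frame(chrom = "chr1", start = 40000, end = 50000)
  # b = 1 exactly everywhere: never strictly below 1, so the walk is bounded
  # by the chromosome here (100 kb < the 500 kb cap)
  r <- refine_boundaries(cand, sites, genome_fst = 0.2, chrom_length = 100000)
  expect_equal(r$start, 0)
  expect_equal(r$end, 100000)
  # and by the cap on a long chromosome
  sites2 <- data.frame(chrom = "chr1", pos = seq(50, 2e6, by = 100),
                       fst = 0.2, retained = TRUE)
  cand2 <- data.frame(chrom = "chr1", start = 1000000, end = 1010000)
  r2 <- refine_boundaries(cand2, sites2, 0.2, chrom_length = 2e6)
  expect_lte(r2$end - r2$start, 2 * 500000 + 10000)
  expect_gte(r2$end - r2$start, 2 * 500000 - 10000)
})

test_that("refinement clamps at chromosome edges and drops empty candidates", {
  sites <- step_profile(block_start = 0, block_end = 10000)
  cand <- data.frame(chrom = "chr1", start = 0, end = 10000)
  r <- refine_boundaries(cand, sites, mean(sites$fst), chrom_length = 100000)
  expect_gte(r$start, 0)
  expect_lte(abs(r$end - 10000), 1000)

  no_sites <- data.frame(chrom = "chr1", start = 90000, end = 95000)
  sites_empty <- sites[sites$pos < 80000, ]
  expect_null(refine_boundaries(no_sites, sites_empty, 0.2, 100000))
})

test_that("empty 1 kb bins count as below threshold", {
  sites <- step_profile()
  # remove all sites in [52000, 54000): two empty bins stop the right walk
  sites <- sites[!(sites$pos > 52000 & sites$pos <= 54000), ]
  sites$fst[sites$pos > 50000] <- 0.6  # otherwise elevated to the right
  cand <- data.frame(chrom = "chr1", start = 40000, end = 50000)
  r <- refine_boundaries(cand, sites, genome_fst = 0.2, chrom_length = 100000)
  expect_equal(r$end, 52000)
})

test_that("region size honors the 1 kb reporting convention", {
  sites <- step_profile()
  cand <- data.frame(chrom = "chr1", start = 40000, end = 50000)
  r <- refine_boundaries(cand, sites, mean(sites$fst), 100000)
  expect_equal((r$end - r$start) %% 1000, 0)
  expect_equal(r$size_kb, (r$end - r$start) / 1000)
  expect_gte(r$end - r$start, 1000)
})

test_that("coverage filter keeps the 50% boundary inclusive", {
  regions <- data.frame(chrom = "chr1", start = c(0, 20000, 40000),
                        end = c(10000, 30000, 50000))
  mask <- data.frame(chrom = "chr1",
                     start = c(0, 20000, 40000),
                     end = c(6000, 25000, 44000))
  kept <- coverage_filter(regions, mask)
  # 60% kept, exactly 50% kept, 40% dropped
  expect_equal(kept$start, c(0, 20000))
  expect_equal(kept$coverage_fraction, c(0.6, 0.5))
})

test_that("build_regions output is independent of chromosome order and contains peaks", {
  set.seed(21)
  mkprof <- function(ch) {
    pos <- seq(50, 2e5 - 50, by = 100)
    fst <- ifelse(pos > 9e4 & pos <= 1.1e5, 0.7, 0.15)
    data.frame(chrom = ch, pos = pos, fst = fst + rnorm(length(pos), 0, 0.02),
               retained = TRUE)
  }
  sites <- rbind(mkprof("chr1"), mkprof("chr2"))
  outl <- data.frame(chrom = c("chr1", "chr2"), start = c(9e4, 9e4),
                     end = c(1e5, 1e5))
  cl <- c(chr1 = 2e5, chr2 = 2e5)
  r_fwd <- build_regions(outl, sites, genome_fst = 0.2, mask = NULL,
                         chrom_lengths = cl)
  r_rev <- build_regions(outl[2:1, ][order(outl[2:1, ]$chrom), ],
                         sites[order(sites$chrom, sites$pos), ],
                         genome_fst = 0.2, mask = NULL, chrom_lengths = cl)
  expect_equal(r_fwd, r_rev)
  expect_true(all(r_fwd$peak_pos > r_fwd$start & r_fwd$peak_pos <= r_fwd$end))
})
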
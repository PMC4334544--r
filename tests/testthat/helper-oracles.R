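# Independent brute-force oracles, deliberately coded from first principles
# (pairwise haplotype loops, ANOVA mean squares) rather than sharing any code
# path with the package implementation.

# Weir-Cockerham theta for one site from the mean-square formulation:
# MSP (among populations), MSG (within), theta = (MSP-MSG)/(MSP+(nc-1)MSG)
oracle_wc_fst <- function(ac1, n1, ac2, n2) {
  p1 <- ac1 / n1
  p2 <- ac2 / n2
  pbar <- (ac1 + ac2) / (n1 + n2)
  if (pbar == 0 || pbar == 1) return(NA_real_)
  msp <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (2 - 1)
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / ((n1 - 1) + (n2 - 1))
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  (msp - msg) / (msp + (nc - 1) * msg)
}

# mean pairwise difference count between all haplotype pairs within a panel
oracle_pairwise_diffs <- function(haps) {
  n <- ncol(haps)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sum(haps[, i] != haps[, j])
    }
  }
  tot / (n * (n - 1) / 2)
}

# nucleotide diversity per accessible bp: mean pairwise differences / L
oracle_pi <- function(haps, accessible_bp) {
  oracle_pairwise_diffs(haps) / accessible_bp
}

# Watterson's theta per accessible bp
oracle_theta_w <- function(haps, accessible_bp) {
  n <- ncol(haps)
  s <- sum(apply(haps, 1, function(x) length(unique(x)) > 1))
  s / sum(1 / seq_len(n - 1)) / accessible_bp
}

# Dxy: mean pairwise differences between haplotypes from different pops / L
oracle_dxy <- function(haps1, haps2, accessible_bp) {
  tot <- 0
  for (i in seq_len(ncol(haps1))) {
    for (j in seq_len(ncol(haps2))) {
      tot <- tot + sum(haps1[, i] != haps2[, j])
    }
  }
  tot / (ncol(haps1) * ncol(haps2)) / accessible_bp
}

# Tajima's D coded directly from the 1989 definitions
oracle_tajima_d <- function(haps) {
  n <- ncol(haps)
  seg <- apply(haps, 1, function(x) length(unique(x)) > 1)
  s <- sum(seg)
  if (s < 3) return(NA_real_)
  k_hat <- oracle_pairwise_diffs(haps)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (k_hat - s / a1) / sqrt(c1 / a1 * s + c2 / (a1^2 + a2) * s * (s - 1))
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
oracle_mann_whitney <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - nx * (nx + 1) / 2
  u_obs <- u_of(seq_len(nx))
  combos <- utils::combn(nx + ny, nx)
  u_null <- apply(combos, 2, u_of)
  mu <- nx * ny / 2
  mean(abs(u_null - mu) >= abs(u_obs - mu) - 1e-9)
}

# random small genotype pair on one chromosome for equivalence tests
random_pair <- function(n_sites = 30, n_hap = 12, len = 10000) {
  pos <- sort(sample.int(len, n_sites))
  draw <- function() {
    p <- stats::rbeta(n_sites, 0.6, 0.6)
    matrix(stats::rbinom(n_sites * n_hap, 1, rep(p, n_hap)), n_sites, n_hap)
  }
  h1 <- draw(); h2 <- draw()
  poly <- rowSums(cbind(h1, h2)) %in% seq_len(2 * n_hap - 1)
  while (sum(poly) < 3) { # ensure enough informative sites
    h1 <- draw(); h2 <- draw()
    poly <- rowSums(cbind(h1, h2)) %in% seq_len(2 * n_hap - 1)
  }
  list(pop1 = genotype_matrix("chr1", pos[poly], h1[poly, , drop = FALSE]),
       pop2 = genotype_matrix("chr1", pos[poly], h2[poly, , drop = FALSE]),
       len = len)
}

# standard small four-region recovery configuration used across tests
recovery_config <- function(seed, n_chrom = 8, chrom_len = 5e6) {
  cl <- stats::setNames(rep(chrom_len, n_chrom), paste0("chr", seq_len(n_chrom)))
  cats <- c("sweep_pop1", "sweep_pop2", "background_selection",
            "reduced_gene_flow")
  regs <- lapply(seq_len(min(4, n_chrom)), function(i) {
    planted_region(paste0("chr", i), 2.4e6, 2.5e6, cats[i])
  })
  simulation_config(seed = seed, chrom_lengths = cl, snp_density = 7,
                    regions = regs)
}
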
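#' Configuration for the two-population divergence simulator
#'
#' Defines the study design emulated by [simulate_pair()]: two populations of
#' `n_haplotypes_per_pop` phased haplotypes (six diploid individuals each by
#' default), independent biallelic SNPs at a given density, background
#' divergence controlled by a Balding-Nichols `F`, an accessibility mask, and
#' optional planted regions carrying one of four molecular signatures.
#'
#' @param seed integer seed; the simulation is fully reproducible given the
#'   configuration.
#' @param n_haplotypes_per_pop haplotypes sampled per population (default 12,
#'   i.e. six diploid individuals).
#' @param chrom_lengths named or unnamed integer vector of chromosome lengths
#'   in bp; unnamed chromosomes are called `chr1`, `chr2`, ...
#' @param snp_density target segregating sites per kb per population
#'   (realistic range 3-10).
#' @param background_fst Balding-Nichols `F` for background sites, in (0,1).
#' @param accessible_fraction fraction of each chromosome accessible to
#'   genotyping, in (0,1]; the mask is drawn as random accessible tiles.
#' @param regions list of [planted_region()] objects; must lie within
#'   chromosome bounds and not overlap one another.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_haplotypes_per_pop = 12L,
                              chrom_lengths = c(chr1 = 5e6),
                              snp_density = 5,
                              background_fst = 0.2,
                              accessible_fraction = 0.9,
                              regions = list()) {
  chrom_lengths <- as.double(chrom_lengths)
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == "")) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (!(background_fst > 0 && background_fst < 1)) {
    stop("background_fst must be in (0,1)")
  }
  if (!(accessible_fraction > 0 && accessible_fraction <= 1)) {
    stop("accessible_fraction must be in (0,1]")
  }
  if (snp_density <= 0) stop("snp_density must be positive")
  for (r in regions) {
    if (!inherits(r, "planted_region")) stop("regions must be planted_region objects")
    if (!r$chrom %in% names(chrom_lengths)) {
      stop("planted region on unknown chromosome: ", r$chrom)
    }
    if (r$end > chrom_lengths[[r$chrom]]) {
      stop("planted region exceeds chromosome bounds: ", r$chrom)
    }
  }
  if (length(regions) > 1) {
    df <- do.call(rbind, lapply(regions, function(r)
      data.frame(chrom = r$chrom, start = r$start, end = r$end)))
    df <- df[order(df$chrom, df$start), ]
    same <- df$chrom[-1] == df$chrom[-nrow(df)]
    if (any(same & df$start[-1] < df$end[-nrow(df)])) {
      stop("planted regions must not overlap")
    }
  }
  structure(list(seed = as.integer(seed),
                 n_haplotypes_per_pop = as.integer(n_haplotypes_per_pop),
                 chrom_lengths = chrom_lengths,
                 snp_density = snp_density,
                 background_fst = background_fst,
                 accessible_fraction = accessible_fraction,
                 regions = regions),
            class = "simulation_config")
}

#' A region planted with a specific molecular signature
#'
#' Categories mirror the four signatures read by the downstream classifier:
#' `sweep_pop1` / `sweep_pop2` (selective sweep in one population: locally
#' reduced segregating-site density and an excess of rare alleles there, so
#' Tajima's D drops in that population only while FST rises),
#' `background_selection` (the same skew in both populations), and
#' `reduced_gene_flow` (elevated between-population divergence with a
#' neutral-looking site-frequency spectrum in both populations).
#'
#' @param chrom chromosome name.
#' @param start,end 0-based half-open bounds in bp.
#' @param category one of `"sweep_pop1"`, `"sweep_pop2"`,
#'   `"background_selection"`, `"reduced_gene_flow"`.
#' @param strength positive effect-size scalar. For sweeps and background
#'   selection it scales the rare-allele skew (default 8); for reduced gene
#'   flow it is the fraction of region sites whose population frequencies are
#'   drawn independently (default 1 = all).
#' @return A `planted_region` list.
#' @export
planted_region <- function(chrom, start, end, category, strength = NULL) {
  category <- match.arg(category, c("sweep_pop1", "sweep_pop2",
                                    "background_selection", "reduced_gene_flow"))
  if (is.null(strength)) {
    strength <- if (category == "reduced_gene_flow") 1 else 8
  }
  if (end <= start) stop("planted region must have end > start")
  if (strength <= 0) stop("strength must be positive")
  structure(list(chrom = as.character(chrom), start = as.double(start),
                 end = as.double(end), category = category,
                 strength = strength),
            class = "planted_region")
}

# ancestral allele frequency: Beta(0.5, 0.5) truncated to [0.02, 0.98],
# a standing-variation-like spectrum without a coalescent dependency
rtrunc_beta <- function(n, lo = 0.02, hi = 0.98, shape = 0.5) {
  stats::qbeta(stats::runif(n, stats::pbeta(lo, shape, shape),
                            stats::pbeta(hi, shape, shape)), shape, shape)
}

# Balding-Nichols population frequency given ancestral p and divergence F
rbn <- function(p, f) stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)

# frequencies in a swept population: with prob. 0.5 the site hitchhiked to
# local fixation (towards the ancestral major allele), otherwise it is a
# post-sweep rare variant
r_swept <- function(p_anc, strength) {
  n <- length(p_anc)
  fixed <- stats::runif(n) < 0.5
  out <- stats::rbeta(n, 0.5, 0.5 * (1 + strength))
  out[fixed] <- as.double(stats::runif(sum(fixed)) < p_anc[fixed])
  out
}

# draw an accessibility mask as random accessible 500 bp tiles, merged;
# emulates fine-grained repeat/CNV masking rather than long assembly gaps
draw_mask <- function(chrom_lengths, accessible_fraction, tile = 500L) {
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    n_tiles <- ceiling(len / tile)
    acc <- stats::runif(n_tiles) < accessible_fraction
    if (!any(acc)) acc[sample.int(n_tiles, 1L)] <- TRUE  # never fully masked
    starts <- (which(acc) - 1L) * tile
    ends <- pmin(starts + tile, len)
    runs <- cumsum(c(TRUE, diff(which(acc)) != 1L))
    runs <- factor(runs, levels = unique(runs))
    data.frame(chrom = ch,
               start = as.double(tapply(starts, runs, min)),
               end = as.double(tapply(ends, runs, max)),
               row.names = NULL)
  })
  out <- do.call(rbind, out)
  out$start <- as.double(out$start); out$end <- as.double(out$end)
  out
}

#' Simulate a diverging population pair with planted signature regions
#'
#' Background sites draw an ancestral frequency from a truncated Beta(0.5,0.5)
#' spectrum and each population's frequency from a Balding-Nichols Beta with
#' `F = background_fst`; haplotype alleles are then Bernoulli draws. Planted
#' regions replace the per-population frequency draws according to their
#' category (see [planted_region()]). Sites monomorphic across the pooled pair
#' are not emitted. Sites are placed only within the accessibility mask.
#'
#' @param config a [simulation_config()].
#' @return A list of class `sim_pair` with elements `pop1` and `pop2`
#'   ([genotype_matrix()] objects over the same loci), `truth` (data frame of
#'   planted regions: chrom, start, end, category), `mask` (accessible
#'   intervals: chrom, start, end; 0-based half-open) and `config`.
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_haplotypes_per_pop
  mask <- draw_mask(config$chrom_lengths, config$accessible_fraction)

  per_chrom <- lapply(names(config$chrom_lengths), function(ch) {
    m <- mask[mask$chrom == ch, , drop = FALSE]
    acc_bp <- sum(m$end - m$start)
    # candidate density is inflated so that, after dropping sites monomorphic
    # within a population, realized per-population segregating density is
    # close to snp_density
    n_cand <- stats::rpois(1L, acc_bp / 1000 * config$snp_density * 1.4)
    if (n_cand == 0L) return(NULL)
    off <- sort(sample.int(acc_bp, min(n_cand, acc_bp)))
    cum <- cumsum(m$end - m$start)
    iv <- findInterval(off - 0.5, c(0, cum))
    pos <- m$start[iv] + (off - c(0, cum)[iv])  # 1-based position
    S <- length(pos)

    p_anc <- rtrunc_beta(S)
    f <- config$background_fst
    p1 <- rbn(p_anc, f)
    p2 <- rbn(p_anc, f)
    for (r in config$regions) {
      if (r$chrom != ch) next
      in_r <- pos > r$start & pos <= r$end
      k <- sum(in_r)
      if (k == 0L) next
      if (r$category == "reduced_gene_flow") {
        hit <- in_r & stats::runif(S) < min(1, r$strength)
        kk <- sum(hit)
        # divergent sorting of standing variation: mirrored ancestral
        # frequencies (q, 1-q) maximize between-population divergence while
        # each population's marginal site-frequency spectrum stays neutral
        anc_r <- rtrunc_beta(kk)
        p1[hit] <- rbn(anc_r, f)
        p2[hit] <- rbn(1 - anc_r, f)
      } else if (r$category == "sweep_pop1") {
        p1[in_r] <- r_swept(p_anc[in_r], r$strength)
      } else if (r$category == "sweep_pop2") {
        p2[in_r] <- r_swept(p_anc[in_r], r$strength)
      } else { # background_selection
        p1[in_r] <- r_swept(p_anc[in_r], r$strength)
        p2[in_r] <- r_swept(p_anc[in_r], r$strength)
      }
    }
    h1 <- matrix(stats::rbinom(S * n, 1L, rep(p1, n)), S, n)
    h2 <- matrix(stats::rbinom(S * n, 1L, rep(p2, n)), S, n)
    seg <- rowSums(cbind(h1, h2)) %in% seq_len(2L * n - 1L)
    list(chrom = rep(ch, sum(seg)), pos = pos[seg],
         h1 = h1[seg, , drop = FALSE], h2 = h2[seg, , drop = FALSE])
  })
  per_chrom <- Filter(Negate(is.null), per_chrom)
  chrom <- unlist(lapply(per_chrom, `[[`, "chrom"), use.names = FALSE)
  pos <- unlist(lapply(per_chrom, `[[`, "pos"), use.names = FALSE)
  h1 <- do.call(rbind, lapply(per_chrom, `[[`, "h1"))
  h2 <- do.call(rbind, lapply(per_chrom, `[[`, "h2"))

  truth <- if (length(config$regions)) {
    do.call(rbind, lapply(config$regions, function(r)
      data.frame(chrom = r$chrom, start = r$start, end = r$end,
                 category = r$category, stringsAsFactors = FALSE)))
  } else {
    data.frame(chrom = character(), start = double(), end = double(),
               category = character(), stringsAsFactors = FALSE)
  }

  structure(list(pop1 = genotype_matrix(chrom, pos, h1, label = "pop1"),
                 pop2 = genotype_matrix(chrom, pos, h2, label = "pop2"),
                 truth = truth, mask = mask, config = config),
            class = "sim_pair")
}

#' @export
print.sim_pair <- function(x, ...) {
  cat(sprintf("sim_pair: %d shared loci, %d planted region(s), seed %d\n",
              length(x$pop1$pos), nrow(x$truth), x$config$seed))
  invisible(x)
}

#' Write planted-region ground truth as BED6
#'
#' @param truth data frame with chrom, start, end, category (as produced in
#'   `sim_pair$truth`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  if (!nrow(truth)) {
    file.create(path)
    return(invisible(path))
  }
  df <- data.frame(truth$chrom, format_bp(truth$start), format_bp(truth$end),
                   truth$category, 0L, ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a planted-region truth BED6 file
#' @param path file written by [write_truth_bed()].
#' @return data frame with chrom, start, end, category.
#' @export
read_truth_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(), start = double(), end = double(),
                      category = character(), stringsAsFactors = FALSE))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  data.frame(chrom = df[[1]], start = df[[2]], end = df[[3]],
             category = df[[4]], stringsAsFactors = FALSE)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)
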
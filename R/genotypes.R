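#' Genotype matrix for one population
#'
#' A light container for biallelic SNP haplotypes of a single population:
#' per-site chromosome and 1-based position plus a sites-by-haplotypes 0/1
#' matrix (`NA` = missing allele call). Diploid individuals are consecutive
#' haplotype column pairs (columns 1-2 = individual 1, and so on).
#'
#' @param chrom character vector of chromosome names, one per site.
#' @param pos integer vector of 1-based positions, strictly increasing within
#'   each chromosome.
#' @param haps integer or logical matrix, sites x haplotypes, values 0/1/NA.
#' @param label population label used in reports.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(chrom, pos, haps, label = "pop") {
  haps <- as.matrix(haps)
  chrom <- rep_len(as.character(chrom), nrow(haps))
  stopifnot(length(pos) == nrow(haps))
  if (any(!haps %in% c(0L, 1L, NA))) {
    stop("haplotype matrix must contain only 0, 1 or NA")
  }
  pos <- as.integer(pos)
  ord <- order(chrom, pos)
  if (is.unsorted(ord)) {
    chrom <- chrom[ord]; pos <- pos[ord]; haps <- haps[ord, , drop = FALSE]
  }
  if (any(stats::ave(pos, chrom, FUN = function(x) c(1L, diff(x))) <= 0L)) {
    stop("positions must be strictly increasing within each chromosome")
  }
  structure(list(chrom = as.character(chrom), pos = pos,
                 haps = haps, label = label),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix '%s': %d sites, %d haplotypes, %d chromosome(s)\n",
              x$label, nrow(x$haps), ncol(x$haps), length(unique(x$chrom))))
  invisible(x)
}

#' Per-site allele counts
#'
#' @param gm a [genotype_matrix()].
#' @return A list with `ac` (count of the alternate/derived allele) and `an`
#'   (number of non-missing allele calls) per site.
#' @export
allele_counts <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  list(ac = as.integer(rowSums(gm$haps == 1L, na.rm = TRUE)),
       an = as.integer(rowSums(!is.na(gm$haps))))
}

#' Number of haplotypes in the panel
#' @param gm a [genotype_matrix()].
#' @return integer.
#' @export
n_haplotypes <- function(gm) ncol(gm$haps)

# subset a genotype_matrix by a logical/integer site index
subset_sites <- function(gm, idx) {
  structure(list(chrom = gm$chrom[idx], pos = gm$pos[idx],
                 haps = gm$haps[idx, , drop = FALSE], label = gm$label),
            class = "genotype_matrix")
}
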
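#' Read a two-column sample-to-population map
#'
#' @param path TSV with columns: sample name, population label (no header).
#' @return Data frame with `sample` and `population`.
#' @export
read_popmap <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  stats::setNames(df[, 1:2], c("sample", "population"))
}

#' Read a BED3+ interval file
#'
#' @param path BED file (0-based half-open; comment lines starting with `#`
#'   are skipped).
#' @return Data frame with chrom, start, end (and `name` when present).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df
}

#' Write intervals as BED (3 or 6 columns)
#'
#' @param df data frame with chrom, start, end and optionally a `name`
#'   column (written as BED6 with score 0 and strand `.`).
#' @param path output path.
#' @param header optional named character vector written as `#key=value`
#'   comment lines.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(sprintf("#%s=%s", names(header), header), con)
  }
  if (nrow(df)) {
    out <- data.frame(df$chrom, format_bp(df$start), format_bp(df$end))
    if ("name" %in% names(df)) out <- cbind(out, df$name, 0L, ".")
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write a table as TSV with a commented header
#'
#' @param df data frame.
#' @param path output path.
#' @param header optional named character vector written as `#key=value`
#'   lines before the column header.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(sprintf("#%s=%s", names(header), header), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-interval recombination-rate map
#'
#' @param path TSV with columns chrom, start, end, rho (header optional,
#'   detected from the first line).
#' @return Data frame with chrom, start, end, rho.
#' @export
read_rho_map <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("chrom", first, ignore.case = TRUE)
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE)
  stats::setNames(df[, 1:4], c("chrom", "start", "end", "rho"))
}

#' Write a simulated pair as VCF + sidecar files
#'
#' Emits a VCFv4.2 file (both populations, GT fields, diploid individuals
#' from consecutive haplotype pairs), a sample-to-population map, a BED3
#' accessibility mask and a BED6 truth file of the planted regions.
#'
#' @param sim a `sim_pair` from [simulate_pair()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix (default `"sim"`).
#' @return Named character vector of the paths written.
#' @importClassesFrom vcfR vcfR
#' @export
write_sim_vcf <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt_strings <- function(h) {
    k <- ncol(h) / 2
    vapply(seq_len(k), function(i) {
      paste(h[, 2 * i - 1], h[, 2 * i], sep = "|")
    }, character(nrow(h)))
  }
  g1 <- gt_strings(sim$pop1$haps); g2 <- gt_strings(sim$pop2$haps)
  if (is.null(dim(g1))) { g1 <- t(g1); g2 <- t(g2) }
  samples <- c(paste0("pop1_ind", seq_len(ncol(g1))),
               paste0("pop2_ind", seq_len(ncol(g2))))
  gt <- cbind("GT", g1, g2)
  colnames(gt) <- c("FORMAT", samples)
  fix <- cbind(CHROM = sim$pop1$chrom, POS = format_bp(sim$pop1$pos),
               ID = ".", REF = "A", ALT = "T", QUAL = ".", FILTER = "PASS",
               INFO = ".")
  meta <- c("##fileformat=VCFv4.2",
            sprintf("##contig=<ID=%s,length=%s>",
                    names(sim$config$chrom_lengths),
                    format_bp(sim$config$chrom_lengths)),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  vcf <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  paths <- c(vcf = file.path(dir, paste0(prefix, ".vcf.gz")),
             popmap = file.path(dir, paste0(prefix, ".popmap.tsv")),
             mask = file.path(dir, paste0(prefix, ".mask.bed")),
             truth = file.path(dir, paste0(prefix, ".truth.bed")))
  vcfR::write.vcf(vcf, paths[["vcf"]])
  utils::write.table(data.frame(samples,
                                rep(c("pop1", "pop2"),
                                    c(ncol(g1), ncol(g2)))),
                     paths[["popmap"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_bed(sim$mask, paths[["mask"]])
  write_truth_bed(sim$truth, paths[["truth"]])
  paths
}

#' Read a VCF into per-population genotype matrices
#'
#' Keeps biallelic SNPs only (single-base REF and ALT), drops indels and
#' multi-allelic records, and optionally drops sites outside an
#' accessibility mask. Phased and unphased diploid GT fields are accepted;
#' missing alleles become `NA`.
#'
#' @param path VCF(.gz) path.
#' @param popmap data frame from [read_popmap()], or a path to one. Exactly
#'   two populations are expected.
#' @param mask optional accessible intervals (data frame chrom, start, end,
#'   0-based half-open) or a BED path.
#' @return List with `pop1` and `pop2` [genotype_matrix()] objects (in
#'   order of first appearance in the popmap).
#' @export
read_vcf_pair <- function(path, popmap, mask = NULL) {
  if (is.character(popmap)) popmap <- read_popmap(popmap)
  if (is.character(mask)) mask <- read_bed(mask)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  keep <- vcfR::is.biallelic(vcf) &
    vcf@fix[, "REF"] %in% c("A", "C", "G", "T") &
    vcf@fix[, "ALT"] %in% c("A", "C", "G", "T")
  vcf <- vcf[keep, ]
  chrom <- vcf@fix[, "CHROM"]
  pos <- as.integer(vcf@fix[, "POS"])
  if (!is.null(mask) && length(pos)) {
    acc <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(mask))) {
      acc <- acc | (chrom == mask$chrom[i] &
                      pos > mask$start[i] & pos <= mask$end[i])
    }
    vcf <- vcf[acc, ]
    chrom <- chrom[acc]; pos <- pos[acc]
  }
  gt <- vcfR::extract.gt(vcf)
  missing <- setdiff(popmap$sample, colnames(gt))
  if (length(missing)) {
    stop("samples in popmap missing from VCF: ", paste(missing, collapse = ", "))
  }
  pops <- unique(popmap$population)
  if (length(pops) != 2) stop("popmap must define exactly two populations")
  hap_matrix <- function(samples) {
    cols <- gt[, samples, drop = FALSE]
    a1 <- matrix(substr(cols, 1, 1), nrow(cols))
    a2 <- matrix(substr(cols, 3, 3), nrow(cols))
    k <- length(samples)
    h <- matrix(NA_character_, nrow(cols), 2 * k)
    h[, seq(1, 2 * k, 2)] <- a1  # ind1 hap a, ind1 hap b, ind2 hap a, ...
    h[, seq(2, 2 * k, 2)] <- a2
    suppressWarnings(matrix(as.integer(h), nrow(cols)))
  }
  out <- lapply(pops, function(p) {
    gm <- hap_matrix(popmap$sample[popmap$population == p])
    genotype_matrix(chrom, pos, gm, label = p)
  })
  names(out) <- c("pop1", "pop2")
  out
}

#' Count gene annotations overlapping each region
#'
#' Half-open interval intersection: an overlap of at least 1 bp counts.
#'
#' @param regions data frame of regions (chrom, start, end; 0-based
#'   half-open).
#' @param genes gene annotations: a data frame (chrom, start, end, optional
#'   name; 0-based half-open), a `GRanges`, or a GFF3/BED file path (read
#'   with `rtracklayer` conventions via [read_bed()] for BED and
#'   [utils::read.table()] for GFF3, converting GFF3's 1-based closed
#'   coordinates).
#' @return `regions` with `n_genes` and a comma-separated `genes` column.
#' @export
intersect_genes <- function(regions, genes) {
  if (is.character(genes)) {
    if (grepl("\\.gff3?(\\.gz)?$", genes, ignore.case = TRUE)) {
      g <- utils::read.table(genes, sep = "\t", comment.char = "#",
                             stringsAsFactors = FALSE)
      genes <- data.frame(chrom = g[[1]], start = g[[4]] - 1, end = g[[5]],
                          name = sub(".*(ID|Name)=([^;]+).*", "\\2", g[[9]]),
                          stringsAsFactors = FALSE)
    } else {
      genes <- read_bed(genes)
    }
  }
  if (!methods::is(genes, "GRanges")) {
    gr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1, genes$end))
    nm <- if ("name" %in% names(genes)) genes$name else
      paste0("gene", seq_len(nrow(genes)))
  } else {
    gr <- genes
    nm <- if (!is.null(names(gr))) names(gr) else
      paste0("gene", seq_along(gr))
  }
  q <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start + 1, regions$end))
  hits <- GenomicRanges::findOverlaps(q, gr)
  regions$n_genes <- 0L
  regions$genes <- ""
  if (length(hits)) {
    by_q <- split(nm[S4Vectors::subjectHits(hits)], S4Vectors::queryHits(hits))
    idx <- as.integer(names(by_q))
    regions$n_genes[idx] <- lengths(by_q)
    regions$genes[idx] <- vapply(by_q, paste, character(1), collapse = ",")
  }
  regions
}
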
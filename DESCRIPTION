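Package: divscan
Title: Windowed Divergence Scans and Classification of Divergent Regions in
    Parapatric Population Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-scan toolkit for pairs of diverging populations genotyped
    at biallelic SNPs. Computes per-site and windowed population-genetic
    statistics (Weir-Cockerham FST, nucleotide diversity, Watterson's theta,
    Tajima's D, Dxy), detects outlier windows by combining an empirical
    top-quantile cut with a site-permutation test under false-discovery-rate
    control, merges outlier windows into divergent regions whose borders are
    refined to 1 kb with a barrier-strength walk, and classifies each region
    into one of four evolutionary categories (background selection,
    adaptation in either population, reduced gene flow) from the two
    populations' Tajima's D relative to genome-wide quantile thresholds.
    Includes cross-pair and ecological comparison statistics (shared-outlier
    permutation test, Mann-Whitney region-versus-genome contrasts, Shannon
    diversity and quantitative Jaccard community distance, partial Mantel
    isolation-by-adaptation test) and a two-population Balding-Nichols
    simulator that plants regions carrying each molecular signature, so the
    whole pipeline is testable against known truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    geosphere,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
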
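---
title: "Methods: windowed divergence scans and the classification of divergent regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed divergence scans and the classification of divergent regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divscan)
```

## Scope and model

`divscan` analyses pairs of diverging populations — the motivating setting is
parapatric lake and river ecotypes of three-spined stickleback, sampled as a
handful of deeply sequenced genomes per population (twelve haplotypes each) —
and asks where along the genome differentiation is exceptional, and which
evolutionary mechanism each exceptional region is most consistent with:
background selection, positive selection (local adaptation) in one
population, or a local restriction of gene flow.

The workflow has five stages.

1. **Windowed statistics.** Per-site Weir–Cockerham $\hat\theta$ (the
   two-population, allele-count form appropriate for phased haplotypes) is
   averaged in non-overlapping windows (10 kb by default). Within-population
   diversity $\pi$, Watterson's $\Theta_W$, Tajima's $D$ and between-population
   $D_{xy}$ are computed per window, with $\pi$, $\Theta_W$ and $D_{xy}$
   divided by the *accessible* base pairs under the user mask rather than the
   nominal window length. FST windows average only sites whose pooled
   minor-allele frequency is at least 0.25 (uninformative polymorphism is
   excluded from the scan; diversity statistics use all sites). Negative
   per-site FST values are retained in window means. Tajima's $D$ is reported
   missing below three segregating sites.
2. **Outlier windows.** Two branches intersect: windows strictly above the
   empirical 99% quantile (type-7 interpolation) of window FST, and windows
   significant in a site-permutation test — per-site FST values are shuffled
   genome-wide, window means recomputed, and each window is compared against
   permuted windows carrying the same number of retained sites — after
   Benjamini–Hochberg control at FDR 0.01.
3. **Region building.** Adjacent outlier windows merge into candidate
   regions. Within each candidate the site of maximal FST (leftmost on ties)
   seeds an outward walk in 1 kb bins. Each bin's barrier strength
   $b = \frac{f/(1-f)}{F/(1-F)}$ compares the bin mean $f$ to the genome-wide
   mean $F$; a side's margin is set at the inner edge of the first of two
   consecutive bins with $b < 1$. Refined regions overlapping each other are
   merged, and regions with less than 50% accessible sequence are discarded.
4. **Classification.** Each region's Tajima's $D$ is computed per population
   over the region's exact refined extent and compared with the 5% and 95%
   quantiles of the genome-wide 100 kb-window $D$ distribution of the same
   population. Both below q05: background selection. Exactly one below q05:
   adaptation in that population. Both within [q05, q95]: reduced gene flow.
   Anything else (a value above q95 with neither below q05, or missing $D$):
   unclassified — an explicit fifth outcome, since the four rules are not
   exhaustive.
5. **Comparative statistics.** Shared-outlier permutation test across pairs,
   window-FST correlations, Mann–Whitney contrasts of regions against the
   genome (Bonferroni-adjusted family threshold, default $\alpha/m = 0.005$),
   recombination-map filtering ($\rho > 100$ between adjacent SNPs dropped,
   window means divided by $\Theta$), Shannon diversity and quantitative
   Jaccard (Ružička) distances of 4th-root-transformed parasite counts,
   haversine geodetic distances, and a partial Mantel test of
   isolation-by-adaptation.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `window_size` | 10 kb | scan resolution; 100 kb gives qualitatively identical scans |
| `td_window_size` | 100 kb | windows defining the classifier's genome-wide D quantiles |
| `maf_threshold` | 0.25 | pooled minor-allele frequency below which sites are excluded from FST |
| `top_q` | 0.01 | empirical tail defining putative outlier windows |
| `fdr` | 0.01 | Benjamini–Hochberg level for the permutation branch |
| `n_perm` | 10^4 | genome-wide shuffles; 10^6 is the faithful full-scale setting |
| `bin` | 1 kb | barrier-strength walk resolution (region borders reported to 1 kb) |
| `max_extension` | 500 kb | walk cap per side; prevents unbounded walks on flat profiles |
| `min_coverage` | 0.5 | minimum accessible fraction for a region to be kept |

## Numerical choices

* Quantiles everywhere are type-7 (R's default), so results are reproducible
  bit for bit.
* The permutation p-value uses the add-one estimator
  $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + \#\text{null})$, never zero.
* Site-count stratification of the permutation null pools windows by exact
  retained-site count when that bin holds enough draws, and otherwise absorbs
  the nearest counts until it does. The scan raises the per-bin draw floor to
  roughly $10/(\text{fdr} \times \text{top}_q)$: the smallest achievable
  p-value must sit below the Benjamini–Hochberg threshold at the rank where
  the empirical branch places true outliers, otherwise the permutation branch
  can never confirm an outlier at desk-scale permutation counts. At $10^6$
  permutations the exact-count stratification is recovered unchanged.
* Before shuffling, the site-value multiset is sorted, which makes
  permutation p-values exactly invariant to any site relabeling that
  preserves the values and the window site counts.
* In the barrier walk, $b = 1$ exactly does **not** stop the walk (the rule
  is "dropped below"), so a profile flat at the genome-wide average runs to
  the extension cap; empty 1 kb bins count as below threshold (no evidence of
  elevated divergence). Peak ties break leftmost for determinism.
* A bin FST of 1 maps to $b = \infty$, treated as above threshold.
* Jackknife window FST enumerates every leave-one-individual-out-per-
  population combination (36 at six versus six diploids) and reports the mean
  and central 95% interval width.

## The synthetic-data generator

The generator is the package's test bed: every downstream stage is exercised
against data with known truth. It is phenomenological by design — no
coalescent or forward simulation, no linkage — and emulates:

* **Background divergence.** Ancestral frequencies from Beta(0.5, 0.5)
  truncated to [0.02, 0.98] (a standing-variation-like spectrum), population
  frequencies from the Balding–Nichols Beta with $F$ = `background_fst`,
  haplotypes as Bernoulli draws, sites monomorphic across the pooled pair
  dropped. Realized scan-window FST tracks $F$ (the MAF-filtered window mean
  at $F = 0.1$ is within ±0.03 of 0.1); the unfiltered per-site mean sits
  lower because conditioning on pooled segregation deflates weak sites.
* **Sweeps** (`sweep_pop1`/`sweep_pop2`): inside the region, the swept
  population's sites either hitchhiked to local fixation (probability 0.5,
  toward the ancestral major allele) or are post-sweep rare variants
  (Beta(0.5, 0.5(1+strength))). Segregating-site density drops and Tajima's
  $D$ goes strongly negative in that population only, while FST rises.
* **Background selection**: the same construction applied to both
  populations independently.
* **Reduced gene flow**: mirrored ancestral frequencies — one population's
  ancestral draw $q$, the other's $1-q$ — which we read as divergent sorting
  of standing variation. Each population's marginal site-frequency spectrum
  is *exactly* the background spectrum (the category's defining neutral
  signature), while between-population divergence is maximal for the
  spectrum. An earlier design that merely decorrelated the two populations'
  draws left region FST well below the sweep categories, so the four
  categories competed unequally for the top-1% cut.
* **Accessibility**: random accessible 500 bp tiles covering
  `accessible_fraction` of each chromosome, merged into intervals. The fine
  granularity emulates repeat/CNV masking; coarser tiles (≥ 1 kb) create
  fully-masked 1 kb bin pairs that legitimately stop the boundary walk and
  fragment refined regions, which is worth knowing when applying the method
  to genomes with long assembly gaps.

What the generator does **not** emulate: linkage disequilibrium and
hitchhiking structure (sites are independent), demography beyond a single
divergence parameter, mutation-rate variation, genotyping error and missing
data patterns. Passing recovery tests therefore demonstrates the pipeline's
statistical logic, not robustness to every property of real resequencing
data.

## Validation scales

The test suite and the acceptance script run desk-scale versions of the
experiments: 1,000 random ≤50-site instances for estimator equivalence
(tolerance 1e-10 against brute-force oracles); 50 null genomes of 2,000
windows with 1,000 permutations each for false-discovery calibration (the
script uses 30); 20 simulation seeds with one planted 100 kb region per
category each (20 regions per category) for recovery — detection and label
agreement are both required to reach 80%, boundary Jaccard median 0.5; 500
null draws for partial-Mantel type-I error at six populations, where the
permutation distribution is enumerated exactly (720 label permutations).
The planted-region genome (8 × 5 Mb, SNP density 7/kb, background FST 0.2)
places the 40 planted windows at exactly the top-1% budget of its 4,000
windows, so the empirical branch can in principle flag all of them — the
test measures whether the full pipeline actually does.

## Known limitations

* Window FST is the unweighted mean of per-site estimates (the variance-
  component ratio-of-sums is available via `site_fst_table` aggregation by
  hand but is not the default); with few retained sites per window the mean
  is noisy, which the permutation null's site-count stratification accounts
  for.
* The barrier-strength formula follows the constraint that $b = 1$ at the
  genome-wide average; the literature source the statistic alludes to is not
  restated here, and a plain-ratio variant is provided (`formula =
  "ratio"`).
* Region Tajima's $D$ over short refined extents (≪ the 100 kb threshold
  windows) is noisy relative to the 5% quantile rule; classification
  accuracy degrades for regions much smaller than the threshold window.
* Missing genotypes reduce a site's called-allele count; windows mixing very
  different call rates use the rounded mean sample size in Tajima's
  constants, a simplification that matters only with heavy missingness.
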
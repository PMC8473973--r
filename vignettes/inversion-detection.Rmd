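---
title: "Detecting candidate chromosomal inversions from SNP genotypes"
author: "invscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting candidate chromosomal inversions from SNP genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invscan)
```

## The problem

A polymorphic chromosomal inversion suppresses recombination in
heterokaryotypes, so the inverted and non-inverted arrangements accumulate
divergence and are inherited as units — a supergene. In a population sample
of unphased SNP genotypes this produces a joint signature that no single
statistic captures:

* windows of SNPs inside the inversion show a local relatedness structure
  (three karyotype groups) unlike the rest of the genome;
* a PCA restricted to the region separates samples into three clusters —
  the two homokaryotypes and the heterokaryotypes — while a genome-wide PCA
  does not;
* heterokaryotypes are heterozygous at nearly every arrangement-
  differentiated site, so their individual heterozygosity exceeds both
  homokaryote groups; the ancestral (older) arrangement retains more
  within-arrangement diversity than the derived one;
* linkage disequilibrium (r²) is strong across the region when all samples
  are pooled, yet collapses within either homokaryote group, where
  recombination is free.

`invscan` implements this detection-and-validation pipeline for diploid,
biallelic, unphased genotypes (VCF input), together with a generator that
plants inversions with known truth so that every stage is testable without
external data.

## The scan: local PCA windows and classical MDS

The genome is cut into non-overlapping windows of `window_size` SNPs
(remainders dropped, windows never spanning chromosomes). Within each
window, missing genotypes are mean-imputed per locus, loci are centered,
and the sample × sample covariance is formed and scaled by its trace, so
each window contributes unit total variance regardless of its diversity;
the top-2 eigenpairs summarize the window. The distance between windows is
the Frobenius norm between their trace-normalized rank-2 covariance
reconstructions,

$$ d(A,B) \;=\; \bigl\lVert \textstyle\sum_{j=1,2}\lambda^A_j v^A_j v^{A\top}_j
 \;-\; \sum_{j=1,2}\lambda^B_j v^B_j v^{B\top}_j \bigr\rVert_F , $$

which is invariant to eigenvector sign flips and to rotations within
degenerate eigenspaces — raw PC-coordinate differences are not, and would
make the scan platform-dependent. The distance matrix over all windows
genome-wide is embedded by classical (Torgerson) multidimensional scaling
into four axes (`MDS1..MDS4`); negative eigenvalues among the requested
axes are truncated to zero with a warning, and each axis's sign is fixed so
its largest-magnitude loading is positive, making output deterministic.
MDS is run genome-wide (all chromosomes jointly) so that axis values are
comparable across chromosomes; a per-chromosome analysis can be obtained by
subsetting the input.

Outlier windows are flagged per axis with standard boxplot statistics:
Tukey hinges (via `fivenum`) ± 1.5 interquartile ranges, values strictly
outside the fences flagged. Outliers are then grouped per chromosome into
runs, tolerating up to `max_gap_windows` intervening non-outlier windows; a
run of strictly more than `min_outliers` outlier windows becomes a
candidate region, spanning from the first outlier window's start to the
last outlier window's end.

### Choosing the window size: resolution matters

The defaults (`window_size = 15`, `min_outliers = 4`, `max_gap_windows =
5`) suit regions expected to span many windows. A region represented by
`L` SNPs can occupy at most `ceiling(L / window_size) + 1` windows, so a
~26-SNP region (typical for a ~1 Mb inversion under reduced-representation
genotyping) can never produce five outlier windows at 15-SNP resolution.
For such regions, scan at a window size satisfying
`L / window_size > min_outliers + 1` — e.g. `window_size = 5` — rather
than relaxing the outlier-count rule. At that resolution a real region
occupies *adjacent* windows while chance outliers (the heavy-tailed higher
MDS axes of noise windows produce several marginal outliers per axis) are
spatially isolated, so `max_gap_windows = 0` is the matching gap setting;
with it, false regions on divergence-free data are rare while planted
regions are recovered to within one window. The gap tolerance exists for
the many-window regime, where MDS noise can drop single interior windows
out of an otherwise solid run.

## Karyotype validation

For a candidate region, samples are projected on the top-2 PCs of the
region's genotypes (mean-imputed, centered); PC1 is oriented to correlate
positively with alternate-allele dosage so that the cluster matching the
reference alleles sits on the negative side. Samples are clustered on PC1
by *exact* one-dimensional k-means (k = 3), computed by dynamic
programming over the sorted coordinates. We chose the DP formulation over
seeded Lloyd iterations because it is optimal and has no initialization
sensitivity at all: with a rare arrangement (the study regime, q ≈ 0.17,
i.e. ~69/28/3 % karyotype frequencies) any quantile-seeded start places
two centers inside the majority cluster, and Lloyd-style iterations can
lock into splitting it while merging the heterokaryotypes with the rare
homokaryotypes.

Two gates must pass before karyotypes are accepted:

1. **Separation.** The mean silhouette width of the PC1 clusters must
   reach 0.62. A forced 3-way split of unimodal noise sits near 0.55
   (measured 0.53–0.58 across divergence-free simulations), genuinely
   trimodal karyotype data near 0.85 (0.66+ even with a singleton rare
   class); 0.62 is the midpoint of the gap. This gate is what keeps
   selective sweeps and plain noise from being karyotyped.
2. **Heterozygote excess.** The central cluster's mean individual
   heterozygosity must strictly exceed both flanking clusters'.

If the three-cluster model fails, a two-cluster model (same gates, with
the excess required of the upper-dosage cluster) is tried: with n = 142
and q = 0.17 the expected count of the rare homokaryote class is ~4 and in
a non-trivial fraction of samples it is absent entirely, leaving a genuine
REF_HOM/HET geometry. If no model passes, all samples are `UNASSIGNED` —
an explicit outcome, reported as "outlier region, karyotype validation
failed", not an error.

Individual heterozygosity is the number of a sample's heterozygous calls
in the region divided by the number of region loci heterozygous in at
least one sample. The denominator is region-level — shared by all samples
— so the statistic is a comparable fraction in [0, 1]; a per-sample
denominator (each sample's non-missing locus count) is available via a
flag. The karyotype summary reports counts, frequencies over assigned
samples, per-group heterozygosity means and the inferred arrangement
frequency `q = (2·n_ALT + n_HET) / (2·n_assigned)`.

## Linkage disequilibrium

r² is the gametic (haplotype-level) measure estimated from unphased
genotypes by maximum likelihood: for each locus pair, haplotype
frequencies are fitted by EM over the 3×3 genotype table, with the
double-heterozygote cell split between coupling and repulsion phases in
proportion to the current estimates; allele frequencies are fixed by the
margins, so the only free parameter is one haplotype frequency. The EM is
initialized at linkage equilibrium and iterated to a 1e-8 tolerance
(non-convergence is flagged, never hidden). `D = p_AB − p_A p_B` and
`r² = D²/(p_A p_a p_B p_b)` follow from the converged frequencies. A
composite genotypic-correlation r² is not used; pairs where a locus is
monomorphic among the jointly non-missing samples are undefined and
excluded from means, with exclusion counts always reported — this matters
within homokaryote groups, where many region alleles are fixed.

Chromosome-wide tables vectorize the EM across all pairs at once: the 9
genotype-pair counts for every pair are obtained by indicator-matrix
cross-products, and the EM updates run elementwise over the pairs still
unconverged. The scalar and vectorized paths are verified against each
other, and the EM against a brute-force likelihood grid, in the test
suite.

Stratified LD computes the mean region r² pooled over all samples and
separately within each homokaryote group (groups under 5 samples are
skipped with a warning — a 4-sample r² estimate is noise). The LD network
connects locus pairs with r² ≥ 0.4 and then iteratively removes nodes in
LD with fewer than 4 partners until stable — iterative rather than
single-pass, since a single pass leaves nodes violating the stated degree
criterion. Connected components are reported with their genomic spans; a
single component spanning the candidate region is the inversion-consistent
outcome.

`run_validate()` combines four criteria — cluster structure, heterozygote
excess ordering, pooled-vs-within LD contrast (ratio ≥ 3), and a network
component overlapping the region — into a verdict: `SV-consistent` when
all hold, otherwise `sweep-like/ambiguous` (or `under-resolution` below 5
polymorphic SNPs).

## The synthetic-data generator

`simulate_dataset()` emulates the post-genotyping state of a
reduced-representation dataset: by default 142 diploid samples, three
25-Mb chromosomes of 494 SNPs each, and a planted inversion at
12.54–13.7 Mb of chromosome 2 represented by 26 SNPs. Background loci are
in Hardy–Weinberg and linkage equilibrium with allele frequencies uniform
on [0.05, 0.5]. Each sample draws an inverted-arrangement count
`a ~ Binomial(2, q)` (q = 0.17); at region loci its two haplotypes sample
alleles independently from their own arrangement's frequency — free
recombination within an arrangement, none between. That minimal mechanism
produces exactly the signals the pipeline detects (pooled LD without
within-group LD, three PCA clusters, heterokaryote heterozygosity excess);
no coalescent machinery is needed, which keeps the generator exact, fast
and dependency-free.

A fraction `d = 0.9` of region loci is arrangement-differentiated with
allele-frequency difference exactly `delta = 0.8`. The two within-
arrangement minor-allele frequencies are tied by `m_anc + m_inv = 1 −
delta`: the inverted-arrangement minor frequency is drawn uniform with
mean `theta_inv = 0.05` and the ancestral one follows with mean
`theta_anc = 0.15` — the derived arrangement is younger and less diverse,
which is what makes the heterozygosity ordering (HET > REF_HOM > ALT_HOM)
testable. Alleles are coded reference-aligned: the reference allele is the
ancestral-arrangement major allele, as it would be for reads aligned to a
reference genome carrying the common arrangement. Undifferentiated region
loci share one frequency across arrangements. Calls are masked missing at
2%; everything is deterministic under the configured seed, and
`emit_fixture()` writes byte-stable VCF/TSV/YAML fixtures.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: background LD decay and haplotype block
structure, population stratification or admixture (the simulated
background carries no structure at all, which is also why genome-wide PC1
can weakly align with the planted inversion in a way real data's dominant
structure would mask), genotyping error beyond uniform missingness, and
allele-frequency spectra from demography. These do not affect the
operations' correctness but do affect real-data outlier budgets; the
filter counts logged at every stage are the diagnostic when moving to real
inputs.

### Numerical and degenerate-input choices

* Mean imputation before any PCA; windows with zero genotypic variance are
  flagged degenerate and excluded from the distance matrix with a log
  entry.
* Distances are computed without forming n × n reconstructions (inner
  products of eigenvectors), so a scan is O(windows² · samples).
* MDS sign convention and PC sign conventions are fixed deterministically;
  ties in 1-D k-means are resolved by the sorted order, which is itself
  deterministic.
* Tukey fences use `fivenum` hinges; values exactly on a fence are not
  outliers (strict inequality), so constant vectors yield none.
* EM pairs that fail to converge in 1000 iterations return their current
  estimate with `converged = FALSE`.
* Infeasible frequency combinations in the generator (clipping needed to
  keep frequencies in (0, 1)) are clipped and logged.

## Problem sizes used in the packaged checks

The packaged tests and the acceptance script run the full pipeline on the
default study conditions (142 samples × 1,482 SNPs) across 20 simulation
seeds for recovery and 20 for null calibration, verify the EM against a
brute-force likelihood grid on 200 random two-locus tables of 50 samples,
and check MDS exactness on 15 points in four dimensions. These sizes give
stable pass/fail behavior for the 18-of-20-seed properties while keeping a
complete run in the low minutes on a single core.

## Known limitations

* Windows are SNP-count based, not physical-length based; SNP-density
  variation therefore maps into window-span variation.
* The scan's outlier budget grows with the number of MDS axes scanned;
  with few windows the higher axes are heavy-tailed and contribute most of
  the chance outliers.
* Karyotype assignment assumes at most one segregating arrangement per
  region; overlapping or nested inversions are out of scope.
* The within-homokaryote LD contrast is uninformative when a homokaryote
  group has fewer than 5 samples (skipped with a warning), which at low
  arrangement frequency is common for the rare class.
* PLINK-format ingestion is not implemented; VCF is the single input
  dialect.
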
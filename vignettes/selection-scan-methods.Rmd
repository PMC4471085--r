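---
title: "Detecting breed-specific selection with LSBL and the d statistic"
author: "lsblscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting breed-specific selection with LSBL and the d statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsblscan)
```

## The problem

Livestock breeds under sustained artificial selection accumulate
allele-frequency shifts at the loci underlying the selected traits and
at markers linked to them. Given SNP-chip genotypes for three breeds,
we want to locate, for each breed separately, the genomic windows whose
differentiation pattern points at that breed's own branch — not merely
at high overall divergence. `lsblscan` implements this as a pipeline:
quality control, per-locus pairwise F~ST~, two per-breed per-locus
statistics (LSBL and d), window aggregation, empirical outlier calling,
and the intersection of the two statistics' candidate lists.

## Per-locus pairwise F~ST~

All downstream statistics are built from per-locus two-population
Weir–Cockerham variance components: `a` (among populations), `b`
(among individuals within populations), and `c` (within individuals),
with the per-locus estimator $\hat\theta = a/(a+b+c)$. Sample sizes
count genotyped individuals only, and a locus is *defined* for a pair
when both populations contribute at least two genotypes and the locus
is not monomorphic across the pair. Negative $\hat\theta$ values are
retained — truncating them at zero would bias every downstream mean and
standard deviation. Genome-wide (multilocus) values use the
ratio-of-sums $\sum a / \sum (a+b+c)$, the estimator's standard
multilocus form; a mean-of-ratios variant exists behind a flag for
sensitivity checks only.

## LSBL: the branch-length view

For three populations A, B, C the pairwise values at a locus decompose
additively into branch lengths:

$$L_A = \frac{\theta_{AB} + \theta_{AC} - \theta_{BC}}{2},$$

and cyclically for B and C. $L_A$ isolates the allele-frequency change
that happened on A's branch since the three-way split: divergence
shared by the B–C pair cancels out. The three branches always sum to
half the sum of the three pairwise values, an identity the test suite
asserts exactly. The same decomposition applied to genome-wide
pairwise values gives the three-branch phylogeny (`fst_tree()`).

```{r}
lsbl(theta_AB = 0.19, theta_AC = 0.13, theta_BC = 0.14)
```

## The d statistic: the standardized view

For breed $i$, $d_i = \sum_{j \ne i} (\theta_{ij} -
E[\theta_{ij}])/\mathrm{sd}[\theta_{ij}]$: the sum of z-scores of the
two pairwise values involving breed $i$, standardized by the mean and
sample (n−1) standard deviation of each pair's per-locus values.
The standardization set is the *complete-case* locus set — loci where
all three pairwise estimators are defined. This choice makes the
per-breed mean of d exactly zero over that set (a centering property
the suite checks to 1e−8); standardizing on per-pair defined sets
instead would leave small systematic offsets whenever the pairs'
defined sets differ.

LSBL and d respond to the same signal but weight it differently: LSBL
is geometric (differences of raw $\theta$), d is distributional
(deviations in units of each pair's spread). Their agreement is
quantified by `stat_correlation()`, overall and within consecutive
5,000-SNP bins after sorting loci by LSBL — agreement is strongest in
the extreme tail, which is where candidates live.

## Windows, outliers, and merged candidates

Per-SNP scores are noisy; sweeps leave footprints. Each chromosome is
tiled from coordinate 0 with non-overlapping 300-kb windows; windows
with fewer than three scored SNPs are dropped; retained windows are
numbered consecutively genome-wide. The window statistic is the
*mean* of per-SNP values (a max option exists behind a flag; the mean
is more robust to single-SNP artifacts). For each breed and each
statistic, the top $\lceil 0.01 N \rceil$ windows are flagged — the
empirical 99th-percentile rule, realized as a top-count so the answer
is deterministic under ties (ties at the cutoff resolve to the lower
window index). A breed's *merged* candidate set is the intersection of
its LSBL and d window lists: demanding both statistics suppresses
windows that are extreme under only one weighting. Windows flagged in
two or more breeds' merged sets are segregated into a shared-window
report: a shared window indicates a difference *between* two breeds
and cannot be attributed to one branch without external evidence.

Each window records a per-breed peak SNP, the locus with the maximal
per-SNP LSBL (ties to the lowest position). Annotation
(`genes_in_windows()`, `peak_snp_genes()`) maps BED/GFF3 gene
intervals to whole windows and to a configurable neighborhood of the
peak SNP (default 50 kb, the order of the chip's marker spacing).

## Quality control and LD pruning

Loci are kept when pooled-sample MAF > 0.01, pooled-sample exact
Hardy–Weinberg p > 1e−6, and the chromosome is an autosome (1–26);
all inequalities strict, removals attributed to the first failing
criterion in that order. The HWE test is the plain exact conditional
test (no mid-p): given observed allele counts, the p-value sums the
probabilities of all heterozygote counts no more probable than the one
observed. Pooling across breeds is the default because the filter runs
before any per-breed analysis, but a strongly differentiated locus can
fail pooled HWE through the Wahlund effect — in a panel at
F~ST~ ≈ 0.15–0.19 this removes a few percent of loci, preferentially
the most differentiated ones, and biases genome-wide divergence
estimates downward. `qc_config(hwe_scope = "per_population")` tests
within each breed instead (a locus fails if any breed falls at or
below the threshold), which spares differentiated loci and is the
appropriate scope when the quantity of interest is divergence itself.

LD pruning (for PCA and other analyses wanting quasi-independent
markers; the scan itself uses the full post-QC set) slides 25-SNP
windows in steps of 5 per chromosome, repeatedly removing the
lower-MAF member (tie: later position) of the worst pair with dosage
r² > 0.1. Full genome sweeps repeat until a sweep removes nothing.
Running to this fixed point — rather than one pass — guarantees two
properties a single pass cannot: pruning is idempotent, and at the
final state no pair within any window exceeds the threshold. Both are
asserted directly in the tests. r² is computed on genotype dosages
over pairwise-complete observations because chip data are unphased.

## The synthetic-data generator

No real genotypes ship with the package, so the simulator is the test
bed. It emulates the statistical structure of a three-breed chip
panel:

* **Drift**: the Balding–Nichols model. Ancestral frequency $p \sim
  U(0.05, 0.95)$ per locus; population $k$ draws its frequency from
  $\mathrm{Beta}(p(1-F_k)/F_k,\, (1-p)(1-F_k)/F_k)$, whose fixation
  index *is* $F_k$ — so the simulator's divergence is a direct input.
  For two populations the expected pairwise estimate is close to
  $(F_i+F_j)/2$, which the suite verifies by Monte-Carlo recovery.
* **Defaults as study conditions**: labels GMM/AWD/CMF with 161/100/61
  individuals and drift parameters (0.18, 0.20, 0.08), calibrated
  analytically so expected pairwise divergence reproduces a
  0.19 / 0.13 / 0.14 pattern — one high pair and two medium pairs, the
  divergence regime the scan is designed for; 26 autosomes with
  exponential inter-SNP gaps of mean 50 kb, giving ~6 SNPs per 300-kb
  window at chip density.
* **Sweeps**: contiguous blocks per breed in which the target breed's
  frequency is replaced by the ancestral $p$ displaced by $\delta$
  toward the farther boundary (up when $p \le 0.5$, down otherwise),
  clamped to [0.01, 0.99]. A deterministic displacement rather than a
  forward simulation: it creates exactly the branch-specific signal
  the statistics target, with a known truth table for power
  evaluation. Blocks are placed only where they cover at least three
  simulated loci — a sweep footprint spanning fewer markers than a
  window needs is undetectable by construction, and counting such
  blocks in a power denominator would measure marker density rather
  than method power.
* **Determinism**: one RNG stream seeded once, consumed in a fixed
  order (positions, ancestral frequencies, population frequencies,
  sweep placement, genotypes, missingness).

What the generator does *not* emulate: linkage disequilibrium beyond
binomial sampling, recombination-rate variation, ascertainment bias of
chip SNPs, and any realistic demography beyond the fixation-index
calibration. Passing power tests therefore demonstrate that the scan
recovers branch-specific frequency shifts of the planted magnitude at
chip density — not that it would achieve the same power on real data
with LD and complex history.

## Power and leakage

With two planted blocks per breed ($\delta = 0.45$, 300-kb blocks,
$F = 0.05$, 60 individuals per population, ~30,000 loci), essentially
every block is recovered by the target breed's merged set. The
interesting quantity is *leakage*: a non-target breed's d is
systematically inflated inside another breed's sweep, because the
z-score of the shared pair enters its sum; LSBL mostly cancels there,
and the merged intersection suppresses most — but not all — such
windows. We quantify leakage as the fraction of (truth block,
non-target breed) pairs in which the block intersects that breed's
merged set, i.e. the fraction of realized leakage opportunities;
typical runs give about 1 in 12. This residual cross-breed overlap is
a property of the statistics themselves, not an artifact: shared
windows between breeds are exactly why the scan separates them into
their own report.

## Numerical choices and degenerate inputs

* Tolerances: LSBL identities are exact algebra (asserted to 1e−12);
  vectorized vs. scalar estimator agreement to 1e−10; d centering to
  1e−8 (accumulated rounding over tens of thousands of loci).
* Monomorphic loci: undefined for F~ST~ (excluded, never zero-filled);
  undefined r² in pruning counts as unlinked; monomorphic-after-
  imputation loci are dropped from PCA.
* Windows are half-open internally, reported 1-based inclusive;
  zero retained windows is a valid (empty-table) result, not an error.
* PLINK text alleles: the reader orders observed alleles
  alphabetically (first = reference); round-trips are exact for loci
  polymorphic in the sample, which post-QC panels guarantee.
* PCA scales loci by $1/\sqrt{\bar p(1-\bar p)}$ by default (equal
  expected drift variance per locus), with an unscaled option.

## Problem sizes

The shipped tests use simulations of roughly 300–30,000 loci and
25–100 individuals per population: large enough for Monte-Carlo
recovery of drift parameters within ±0.01 and for the power study, and
sized so the whole suite runs comfortably on a laptop. The same code
paths scale linearly in loci and are routinely used at full chip scale
(~50,000 SNPs, hundreds of samples).

## Known limitations

* Three populations only for LSBL (the d statistic generalizes to more,
  the current scan driver does not).
* No haplotype statistics (REHH/XPEHH/RSB) — the scan is purely
  frequency-based.
* The empirical percentile rule provides outlier ranking, not
  significance: no permutation or simulation-calibrated p-values.
* Gene annotation is interval algebra only; it does not consult
  orthology or trait databases.
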
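---
title: "peakforge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{peakforge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

peakforge implements the post-alignment analysis of a paired ATAC-Seq /
RNA-Seq developmental muscle study design: 24 chromatin-accessibility
libraries spanning five developmental stages (gestational days 45, 60 and
90, one week and six weeks of age) and three within-litter piglet size
classes (small, average, large). This vignette documents the statistical
procedures, the defaults and why they were chosen, what the synthetic-data
generator does and does not emulate, and the design decisions taken where
the methodology was genuinely open.

## Consensus peaks

Per-sample peak calls (BED/narrowPeak) are combined by merging every group
of peaks connected by inter-peak gaps of at most `merge_gap = 10` bp
(overlapping and book-ended peaks always merge; the relation is closed
transitively, as in `bedtools merge -d 10`). Each merged peak carries a
*support* value: the number of distinct samples contributing at least one
member peak — a sample contributing two members counts once. Peaks with
support below `min_support = 3` are discarded before any count-based
analysis, which removes sample-private noise calls while keeping anything
reproducible across at least three libraries.

Two invariants are worth stating because downstream code relies on them:
consensus peaks on a chromosome are pairwise separated by more than
`merge_gap`, and the members of all consensus peaks partition the input.
Both are property-tested against a quadratic-time transitive-merge oracle.

Fragment counting assigns a fragment to a peak on ≥ 1 bp overlap.
Because consensus peaks are disjoint a fragment almost always lands in at
most one peak; a long fragment spanning the small gap between two peaks is
counted in both, which is the standard behaviour of interval-overlap
counters.

## Library QC

The quality filter retains fragments with mapping quality ≥ 10, the
proper-pair SAM flag set, none of the unmapped/mate-unmapped/QC-fail/
duplicate bits set, and a non-mitochondrial chromosome — the standard
`samtools view -f2 -q10 -F1548` recipe plus MT exclusion.

* **TSS enrichment score.** The ±1 kb region around each TSS is tiled
  into twenty 100-bp windows. Depth is pooled across TSSs
  (strand-oriented), each window is scored as its mean depth divided by
  the mean depth of the two outermost windows, and the library's TSS-ES is
  the maximum window score. Pooling depth before taking the ratio (rather
  than averaging per-TSS ratios) makes the score well defined when
  individual TSSs have empty flanks; uniform coverage scores exactly 1,
  and the score is invariant to uniform depth rescaling. Depth is
  fragment-overlap coverage, not cut-site counts; a cut-site variant would
  sharpen the profile but the depth-based score is the one defined for
  this analysis.
* **FRiP** is the fraction of filtered fragments overlapping any peak.
* **NRF / PBC1 / PBC2** are computed over distinct fragment
  `(chrom, start, end)` triples — the natural notion of "position" for a
  paired-end library, rather than 5′ ends. PBC2 is undefined (reported as
  `Inf` with a flag) when no position is seen exactly twice.
* **NFR score** is `log2` of the count of sub-nucleosomal fragments
  (< 100 bp) over mono-nucleosome fragments (180–247 bp). The length
  bounds for the nucleosome-free, mono- and di-nucleosome bins
  (< 100, 180–247, 315–473 bp) follow ENCODE conventions; the score's
  exact definition varies between toolkits, so the one used here is
  documented rather than inferred.
* **Binned coverage correlation** counts fragments per 100-bp genome bin
  per sample (a fragment counts in every bin it overlaps) and reports the
  Pearson correlation matrix of the bin vectors.

## Normalization and ordination

Counts over the consensus set are normalized for ordination as
`log2(raw / library_size * 1e8 + 1)`; a raw count of zero maps to zero for
any library size. Sample dissimilarity is the Manhattan distance between
normalized columns.

Non-metric MDS minimizes Kruskal's stress-1,
`sqrt(sum((D - dhat)^2) / sum(D^2))`, where `D` are configuration
distances and `dhat` is the isotonic regression of `D` on the rank order
of the input dissimilarities. The isotonic fit uses pool-adjacent
violators; ties in the input dissimilarities are handled by the primary
approach (tied pairs are ordered by their current configuration distance,
so ties contribute no stress of their own). The configuration is
initialized from classical (Torgerson) scaling — with seeded sub-1e-4
jitter only if the classical solution is rank-deficient — and updated by
alternating the isotonic fit with a Guttman-transform (majorization)
step. The majorization step was chosen over Kruskal's original steepest
descent because each step provably does not increase the raw stress, which
yields the monotone stress sequence the implementation promises and
removes the need for step-size heuristics; iteration stops when the
stress-1 improvement falls below `tol = 1e-6` (default `max_iter = 200`),
or immediately if a step fails to improve stress-1 (whose normalizer,
unlike the raw stress, is configuration-dependent). Solutions are defined
up to rotation/reflection, so tests compare stress values, not raw
coordinates. `k = 3` components reproduce the component-1–3 views used
for visual QC of the study design; PCA of expression uses an SVD
(`prcomp`) with centering and no scaling, and no additional centering or
scaling is applied before NMDS beyond the stated count normalization.

## Differential testing

Differential accessibility across timepoints tests, per consensus peak, a
negative-binomial log-link GLM with design `~ size + time` against the
nested reduced design `~ size`, with log size-factor offsets
(median-of-ratios factors) and a fixed per-feature dispersion. The LRT
statistic `2(ll_full − ll_reduced)` is referred to chi-square with
degrees of freedom equal to the difference in parameter count;
Benjamini–Hochberg step-up adjustment is applied at FDR 10%, and a peak is
reported significant only if additionally its maximum absolute time
log2 fold change exceeds 2. Fold changes are unshrunk maximum-likelihood
estimates; no shrinkage estimator is applied. Day-90 differential
expression tests `~ size` against the intercept with small as reference
(denominator of every fold change); large-vs-small and average-vs-small
come from the fitted coefficients, average-vs-large from their difference,
and the |log2FC| ≥ 0.1 threshold is treated purely as a *reporting*
threshold, not part of the test.

Dispersions are estimated by method of moments on normalized counts,
`max(0, (s² − μ)/μ²)`, then shrunk 50% toward a fitted `a0 + a1/μ`
mean–dispersion trend with a floor of 1e-8. This is a deliberate
simplification of the empirical-Bayes machinery in mainstream count
packages: the aim here is error-rate control, not numerical identity with
any particular implementation. Two calibration facts follow from the
simplification and are asserted by the test suite: at the *generating*
dispersion the LRT's null p-values are uniform with type-I error at the
nominal level, while with *estimated* dispersions the plug-in noise makes
the test mildly conservative (observed type-I below nominal, never
above). Conservative calibration preserves FDR control, at a small cost
in power. Features that fail to converge are flagged and excluded from
the BH denominator; the litter factor can be added as a fixed covariate
(`covariates = "litter"`) but is not in the default design, since the
unbalanced litter structure is heavily confounded with timepoint.

## Annotation and overlay

Peaks are classified into eleven genomic feature categories by fixed
precedence, anchored at the peak midpoint: promoter windows by absolute
distance to the nearest TSS (≤ 1 kb, 1–2 kb, 2–3 kb), then features of the
covering gene (5′ UTR > 3′ UTR > 1st exon > other exon > 1st intron >
other intron), then ≤ 3 kb downstream of a 3′ end, else distal
intergenic. The midpoint anchor is a documented choice — the category
systems in use do not state an anchor — and is configurable in spirit:
classification operates on a single point, so any other anchor can be
obtained by shifting the peak. A documented surjection collapses the
detailed system onto the broad vocabulary used for differential-peak
summaries (Promoter, Proximal, 5′/3′ UTR, CDS, Exonic, Intronic,
Intergenic), where "Proximal" additionally captures distal calls whose
midpoint lies 2–10 kb from the nearest TSS. Percentages are reported to
three significant figures.

The peak-to-gene overlay links each gene to every peak within 10 kb
(strand-aware). The signed distance follows the convention: positive when
the peak lies within the gene or its 5′ 10-kb upstream region, negative
within 10 kb past the 3′ end; the magnitude is the distance from the
gene's 5′ end to the peak's 5′-most boundary. The two prose descriptions
of this coordinate in circulation are mutually inverted; the convention
adopted here is the one consistent with the worked upstream-peak example
(a peak 8769 bp upstream of a TSS has a positive coordinate), and it is
strand-mirror symmetric by construction (property-tested). One TSS per
gene is used (the gene model's 5′ end); annotation sets that distinguish
transcript-level TSSs would shift promoter-window assignments slightly.

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions the pipeline is validated under:

* an unbalanced 24-sample design — one complete litter at day 45 and at
  day 60 (3 samples each), four day-90 litters (12), smallest + largest
  from one litter at 1 week (2), and two partial litters at 6 weeks (4);
* a toy genome of two 1-Mb autosomes plus a 16-kb "MT" (so the
  mitochondrial filter is exercised), with non-overlapping 2–10 kb gene
  models, 1–4 exons each, and UTRs carved from the outermost exons;
* fragment lengths from a three-component normal mixture with means
  50/180/350 bp (sd 15/25/40, weights 0.50/0.35/0.15), emulating the
  nucleosome-free / mono- / di-nucleosome structure of ATAC libraries;
  55% of fragments are centred near TSSs (sd 450 bp), matching the
  TSS-proximal bias of open chromatin, and 10% are built to fail the
  quality filter;
* per-sample peak calls containing a shared core set (55% TSS-proximal,
  per-sample presence 0.9, boundary jitter ≤ 20 bp), five peaks specific
  to each size class, and ten sample-private peaks — all separated by more
  than `merge_gap + 2·jitter`, so the consensus construction provably
  recovers exactly the planted regions and the support filter removes
  exactly the private ones;
* negative-binomial counts with log-normal feature baselines, log-normal
  library factors (log-sd 0.3, forcing non-trivial normalization) and
  dispersion 0.1; 10% of peaks carry a time effect of |log2FC| = 2.5
  concentrated in one randomly chosen non-reference timepoint, and
  affected genes in the expression matrix carry a size effect (full
  magnitude in large, half in average, relative to small).

Determinism is part of the contract: identical configurations (including
the seed) produce byte-identical outputs, and the generators restore the
caller's RNG state.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: sequence content and mappability structure,
GC and transposase insertion bias, copy-number and allelic effects,
correlated dispersion across peaks, peak-calling artefacts (peak calls
are inputs here), and genuine biological covariance between chromatin
accessibility and expression. Planted-truth recovery demonstrates that
the pipeline's operations are correct and calibrated under the stated
stochastic model, not that the model captures everything in a real
library.

## Problem sizes and numerical choices

The validation suite runs at desk scale by design: count matrices of
2000 features × 24 samples for calibration and FDR-control checks
(20 replicates for the false-discovery-proportion summary), a few hundred
features for recovery checks, 10^5 fragments for the fragment-size
Kolmogorov–Smirnov check, and ≤ 200-interval fixtures for the brute-force
oracles. GLM fits use `glm.fit` with a maximum of 50 IRLS iterations;
LRT statistics are floored at zero (convergence tolerance makes tiny
negative values possible); dispersions are floored at 1e-8; BH treats
missing p-values as untested. Degenerate inputs fail loudly: empty
fragment sets, zero library sizes, zero flank depth in the TSS profile,
all-zero features (skipped and flagged), non-nested designs, and
annotation requests that do not fit the genome all raise explicit errors.

## Known limitations

The dispersion estimator trades efficiency for simplicity; with fewer
than ~8 samples its trend fit is unstable and the LRT calibration relies
on the chi-square approximation, which is asymptotic in sample count.
The fixed five-timepoint factor model does not exploit temporal ordering
(no spline/time-course modelling). Peak classification uses a single
midpoint anchor and one TSS per gene. The overlay reports all in-window
(gene, peak) pairs and leaves causal interpretation to the reader.
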
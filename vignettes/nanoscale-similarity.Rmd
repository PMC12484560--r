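---
title: "Comparing nanoscale organisation in SMLM data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing nanoscale organisation in SMLM data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smlmdissim)
```

## The comparison problem

Single-molecule localisation microscopy yields lists of molecular
coordinates with ~10–30 nm precision. Two such datasets are rarely
comparable point-by-point: molecule positions are random draws from an
underlying spatial organisation, and total counts depend on expression
level, labelling efficiency and acquisition length. What is comparable is
the *texture* of the pattern — how localisations distribute over space at
the scale of nanoclusters and filaments. `smlmdissim` reduces each region
of interest to the distribution of localisation counts over occupied 30 nm
bins and compares those distributions with a scaled two-sample
Kolmogorov–Smirnov statistic.

This summary is deliberately insensitive to *where* structures sit (bin
counts are pooled over the ROI, discarding position) and sensitive to *how*
localisations aggregate: tight clusters produce heavy-tailed count
distributions, dispersed patterns produce many singly-occupied bins. The
statistic therefore compares organisation, not morphology or absolute
position; two patterns with the same count distribution but different
spatial arrangement of their bins are indistinguishable to it.

## The score, step by step

1. **Tiling.** Whole-cell localisation tables are cut into square ROIs of
   side 3000 nm on a grid anchored at the lower-left corner of the cell
   boundary's bounding box. Anchoring to the cell (rather than a global
   origin) makes tiling reproducible per cell and translation-equivariant.
   Membership is half-open, `[origin, origin + side)`, so no point is
   counted twice. Only tiles whose overlap with the boundary polygon
   reaches `min_coverage` are kept; the default of 1 keeps fully interior
   tiles only, because the count distribution of a partial tile is biased
   by its missing support. Coverage is computed exactly as the area of the
   rectangle–polygon intersection (Sutherland–Hodgman clipping; the
   point-in-polygon assignment uses `mgcv::in.out`).
2. **Binning.** Each ROI is divided into 30 × 30 nm bins (100 × 100 bins per
   standard ROI). 30 nm matches typical SMLM localisation precision:
   smaller bins would resolve localisation noise, larger bins would wash
   out nanocluster structure. Empty bins are excluded both from the count
   multiset and from the K-S sample size — the sample units are *occupied*
   bins, so the comparison is of how occupied space is used, partially
   decoupled from overall density.
3. **Scoring.** For two ROIs with occupied-bin count ECDFs F and G and
   sample sizes m and n, `D_mn = max |F − G|` is evaluated over the union
   of supports (exact for right-continuous step functions),
   `J = (n + m)/(nm)` rescales for sample size, and
   `c(α) = sqrt(−0.5 ln(α/2))` is the critical scale at level α = 0.05.
   The score `λ = D_mn / (c(α)√J)` is zero for identical distributions and
   exceeds 1 exactly when the classical K-S test rejects at level α.
4. **Aggregation.** Condition pairs report λ̄ ± sd over all cross pairs
   (every reference ROI against every comparison ROI). Self-comparisons
   use distinct unordered pairs and exclude each ROI against itself —
   including the zero diagonal would deflate the within-condition
   variability that the significance test relies on. The standard
   deviation uses the population (divide-by-N) convention, a choice that
   had to be fixed one way; it is recorded in the output so downstream
   users can convert.

## Density normalisation by thinning

Lower-density data score as more similar (fewer occupied bins, flatter
count CDFs), so comparisons across uncontrolled expression levels need
normalisation. Each ROI at or above the standard density of
100 localisations/μm² is randomly subsampled **without replacement** to
exactly that density (900 points for the standard ROI), 100 times; the
count histograms of the subsamples are averaged element-wise, and the mean
occupied-bin count across repeats serves as the K-S sample size (a real
number — the averaged histogram has no integer sample size, and rounding
would arbitrarily shift J). ROIs strictly below the target are excluded
rather than upsampled; an ROI exactly at the target is retained, its
subsample being the full set. Sampling with replacement would fabricate
duplicate localisations and concentrate mass at high counts, which is why
it is not offered.

Thinning is computed once per ROI (histograms averaged, then one λ per
pair) rather than averaging λ over repeats; the per-repeat alternative
converges to a similar location but at 100× the pairwise cost. Per-repeat
RNG streams are derived from `(seed, roi_id, repeat)` via a hash, so
results do not depend on the order in which ROIs are processed — important
when a catalogue is rescored incrementally.

The 100/μm² default balances sensitivity against inclusivity: the tests in
this package show the 10-vs-50-cluster separation shrinking when the
target drops to 25/μm², and a higher target would exclude moderately
expressed proteins.

## Simulators: what they emulate, and what they do not

The generators produce ground-truth patterns for validation:

* `simulate_clusters()` — n cluster centres uniform in the ROI, each
  emitting p isotropic Gaussian deviates (σ per axis). Out-of-ROI deviates
  are **resampled** until inside, preserving exact totals (clipping would
  pile points on the border; discarding would break constant-total
  designs). Centres are uniform over the full ROI, so clusters near edges
  are slightly truncated-then-resampled — at σ = 50 nm and side 3000 nm
  this affects a few percent of clusters and is visible only in extreme
  moment-level tests.
* `simulate_fibres()` — each fibre is a line chord clipped to the ROI
  (random or fixed orientation), points uniform along the chord (or evenly
  spaced), optional perpendicular Gaussian jitter emulating localisation
  precision.
* `simulate_csr()` — uniform points: the homogeneous Poisson null.
* `simulate_mixture()` and the `heterogeneity` hook of
  `simulate_condition()` compose these into mixed or per-ROI-varying
  conditions.

The standard validation design used throughout the tests is 900
localisations per ROI (density 100/μm², the thinning standard) and
σ = 50 nm — a typical nanocluster radius. Cluster-count validation varies
k from 10 to 50 at constant total, so the signal is purely organisational.
These simulators emulate *organisation*, not microscopy: there is no
blinking kinetics, no repeated localisation of one fluorophore, no
localisation-precision scatter (unless added as fibre jitter), no drift,
and no inhomogeneous background. Passing tests therefore demonstrate that
the statistic orders and separates idealised organisations correctly; they
do not certify performance on data with strong multi-blinking artefacts,
which should be grouped/corrected upstream.

## Significance testing

Whether a comparison condition differs from a reference beyond
within-reference variability is decided by a Monte Carlo permutation test
on the pooled pairwise-λ distance matrix (symmetric, zero diagonal). The
test statistic is `mean(inter-group λ) − mean(intra-group λ)`; group
labels are reassigned uniformly at random (sizes preserved) 1000 times by
default, and the p-value is the add-one proportion
`(1 + #{null ≥ observed}) / (1 + N)`, which cannot return zero and keeps
the estimator valid at finite N. The statistic's form was an open design
choice — the mean-difference is transparent and directly interpretable in
λ units; a PERMANOVA-style pseudo-F on squared distances is available via
`statistic = "pseudo_f"` for users who prefer a variance-ratio form.
Permutations are unconstrained; stratified permutation (e.g. within cells)
would be the natural extension when ROIs are not exchangeable.

Note the distance-matrix entries are not independent (they share ROIs),
which is exactly why calibration is verified empirically:
`calibrate_pvalues()` repeats the full generate–score–permute cycle and
compares the p-value ECDF to the uniform diagonal. In this package's
acceptance tests the null calibration uses 500 repeats of two 8-ROI groups
from one 10-cluster condition with 199 permutations per repeat (p-value
granularity 1/200, negligible against the 0.1 sup-distance criterion), and
the power check uses a 10-vs-50-cluster alternative; both sizes were chosen
to make the Monte Carlo error small relative to the assertions they feed.

## Numerical and degenerate-input choices

* Empty ROIs cannot be scored (no occupied bins); they raise a typed error
  rather than returning λ = 0, which would mean "identical".
* The K-S maximum is exact: both step CDFs are evaluated right-continuously
  on the union of supports. A brute-force integer-sweep oracle in the test
  suite confirms equality over randomised toy histograms.
* Points exactly on an ROI's far edge belong to the next tile (half-open
  convention); fibre chords are clipped a relative 1e-12 inside the far
  edge so "even" spacing cannot emit a boundary point.
* Tile coverage is compared against `min_coverage` with a 1e-9 absolute
  tolerance so exact full coverage survives floating-point area
  computation.
* Non-integer thinning targets round half-to-even (base R `round()`).
* Ranked lists break λ̄ ties lexicographically by condition identifier, so
  output order is total and reproducible.
* Pairwise-λ caching keys on a content hash of the two ECDF summaries plus
  (α, thinning flag); cached values are serialised at 17 significant
  digits so they round-trip bit-exactly.

## Limitations

* The occupied-bin count summary discards spatial arrangement beyond the
  bin scale; patterns with matched count histograms but different
  geometries are not distinguished.
* λ's sample-size adjustment J removes the first-order dependence on
  occupied-bin counts, but the underlying discrete ties make the λ > 1
  criterion conservative (empirical type-I well below α under CSR).
* Thinning discards sub-threshold ROIs entirely; conditions with most ROIs
  below 100/μm² lose power or drop out.
* The permutation test treats ROIs as exchangeable units; ROIs from the
  same cell are correlated, and cell-stratified permutation is not yet
  implemented.
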
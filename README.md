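# smlmdissim

Statistical similarity of nanoscale protein organisation in single-molecule
localisation microscopy (SMLM) data.

SMLM experiments (dSTORM, PALM, PAINT, ...) produce point clouds of molecular
coordinates rather than pixel images. A recurring question is whether two
datasets — two proteins, two cell types, two treatments — share the same
*nanoscale organisation*: the same texture of clusters, fibres or dispersion,
independent of where individual molecules happen to sit. `smlmdissim`
implements a Kolmogorov–Smirnov–based dissimilarity score for that question,
together with the surrounding machinery a comparison pipeline needs: ROI
tiling from whole-cell data, density normalisation by thinning, similarity
ranking across a catalogue of conditions, point-pattern simulators, and a
permutation test for statistical significance. It is aimed at microscopists
and image analysts comparing SMLM datasets across experiments or labs.

## The dissimilarity score

Each 3 × 3 μm region of interest (ROI) is divided into 30 × 30 nm bins and
reduced to the multiset of localisation counts over *occupied* bins (bins
with ≥ 1 localisation). Let F(x) and G(x) be the empirical CDFs of these
count distributions for two ROIs, with sample sizes m and n (their
occupied-bin counts). With the two-sample K-S statistic

    D_mn = max_x | F(x) − G(x) |,    J = (n + m) / (n m),
    c(α) = sqrt( −0.5 · ln(α/2) ),

the dissimilarity score is

    λ = D_mn / ( c(α) · sqrt(J) ),    α = 0.05.

λ = 0 means identical count distributions; λ > 1 means the two ROIs differ
significantly at level α (the classical rejection condition
D_mn > c(α)√J); intermediate values rank similarity. Condition-level
comparisons report the mean λ̄ ± sd over all ROI pairs. Because sparser data
score as more similar, a second, density-invariant variant thins every ROI
to a standard 100 localisations/μm² (100 random subsamples, averaged count
histograms) before scoring; ROIs below that density are excluded.

## Worked example

Rank four simulated conditions against a 10-cluster reference (10 ROIs per
condition, 900 localisations per ROI, σ = 50 nm):

```r
library(smlmdissim)
library(purrr)

gen <- function(k) function(seed, ...)
  simulate_clusters(k, total_points = 900, sigma = 50, seed = seed)

reference <- map(simulate_condition(10, gen(10), seed = 1)$roi, roi_ecdf)
catalogue <- list(
  clusters_k10 = map(simulate_condition(10, gen(10), seed = 2)$roi, roi_ecdf),
  clusters_k50 = map(simulate_condition(10, gen(50), seed = 3)$roi, roi_ecdf),
  csr  = map(simulate_condition(10, \(seed, ...) simulate_csr(900, seed = seed),
             seed = 4)$roi, roi_ecdf),
  fibres = map(simulate_condition(10, \(seed, ...) simulate_fibres(6, 150,
               seed = seed), seed = 5)$roi, roi_ecdf)
)
rank_conditions(reference, catalogue)
#> # A tibble: 4 × 5
#>   condition    lambda_bar lambda_sd n_pairs thinned
#>   <chr>             <dbl>     <dbl>   <int> <lgl>
#> 1 clusters_k10      0.327     0.118     100 FALSE
#> 2 fibres            1.26      0.428     100 FALSE
#> 3 clusters_k50      3.81      0.182     100 FALSE
#> 4 csr               6.26      0.165     100 FALSE
```

The independent replicate of the reference pattern ranks first with λ̄ well
below 1 (not significantly different); 50-cluster and fully random patterns
rank far away. A permutation test on the pooled pairwise-λ distance matrix
confirms the 10-vs-50-cluster separation:

```r
dm <- build_distance_matrix(reference, catalogue$clusters_k50)
tidy(permutation_test(dm, n_permutations = 1000, seed = 6))
#> # A tibble: 1 × 4
#>   statistic  p.value method                  n_permutations
#>       <dbl>    <dbl> <chr>                            <dbl>
#> 1      3.55 0.000999 permutation (mean_diff)           1000
```

The statistic is the mean inter-group minus mean intra-group distance
(3.55 λ units); p = 1/1001 is the smallest value 1000 permutations can
produce. Single ROI pairs are scored directly:

```r
r1 <- simulate_clusters(10, points_per_cluster = 90, sigma = 50, seed = 42)
dissimilarity_lambda(r1, simulate_csr(900, seed = 43))
#> # A tibble: 1 × 5
#>    d_mn       j c_alpha alpha lambda
#> 1 0.551 0.00398    1.36  0.05   6.43
```

Real data enter through `read_localisations()` (ThunderSTORM-style, plain
or pixel-unit CSV; HDF5 record arrays), are tiled with `tile_rois()` against
a cell boundary polygon, and optionally density-normalised with
`thin_roi()`/`thin_condition()`. `rank_catalogue()` runs the whole pipeline
over a directory-per-condition catalogue with content-hash caching of
pairwise scores, and `exec/smlmdissim` exposes the same steps as a command
line (`simulate`, `tile`, `rank`, `score`, `thin`, `test`).

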
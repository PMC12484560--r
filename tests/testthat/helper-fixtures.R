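# Shared fixture builders and independent oracles, constructed in code.

# ECDF summary straight from a vector of occupied-bin counts.
ecdf_from_counts <- function(counts) {
  empirical_cdf(frequency_histogram(counts), length(counts))
}

# Independent brute-force K-S oracle: evaluate both step CDFs at every
# integer over the full combined count range and take the max absolute
# difference. Deliberately naive; kept separate from the implementation.
ks_brute_force <- function(a, b) {
  step_at <- function(e, x) {
    if (any(e$support <= x)) max(e$cdf[e$support <= x]) else 0
  }
  xs <- seq(min(a$support, b$support) - 1L, max(a$support, b$support) + 1L)
  max(vapply(xs, function(x) abs(step_at(a, x) - step_at(b, x)), numeric(1)))
}

# An ROI with points placed explicitly (absolute nm within [0, side)).
roi_at <- function(x, y, side = 3000) {
  roi(tibble::tibble(x = x, y = y), side = side)
}

# A square cell boundary with lower-left corner (x0, y0).
square_boundary <- function(size, x0 = 0, y0 = 0, label = "cell") {
  cell_boundary(x = c(x0, x0 + size, x0 + size, x0),
                y = c(y0, y0, y0 + size, y0 + size), label = label)
}

# Random count histogram for oracle sweeps: up to `max_bins` occupied bins
# with counts in 1..max_count.
random_count_ecdf <- function(max_bins = 20, max_count = 12) {
  n <- sample.int(max_bins, 1)
  ecdf_from_counts(sample.int(max_count, n, replace = TRUE))
}

# Simulated condition of k-cluster ROIs at the standard design: 900 total
# points, sigma 50 nm, 3 x 3 um.
cluster_condition <- function(n_rois, k, seed, total_points = 900, sigma = 50) {
  simulate_condition(n_rois, function(seed, ...) {
    simulate_clusters(k, total_points = total_points, sigma = sigma, seed = seed)
  }, seed = seed)
}
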
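test_that("binning assigns points to 30 nm bins and drops empty bins", {
  one <- bin_localisations(roi_at(10, 10))
  expect_equal(as.integer(one), 1L)
  expect_equal(attr(one, "n_occupied"), 1L)

  # 3 points in one bin + 2 in another: counts {3, 2}, total conserved
  r <- roi_at(c(10, 11, 12, 100, 101), c(10, 11, 12, 100, 101))
  counts <- bin_localisations(r)
  expect_setequal(as.integer(counts), c(3L, 2L))
  expect_equal(attr(counts, "n_occupied"), 2L)
  expect_equal(sum(counts), nrow(r))

  empty <- bin_localisations(roi(tibble::tibble(x = numeric(0), y = numeric(0))))
  expect_equal(length(empty), 0)
  expect_equal(attr(empty, "n_occupied"), 0L)

  expect_error(bin_localisations(roi_at(1, 1), bin_side = 29),
               class = "smlm_config_error")
})

test_that("bin counts conserve localisations and respect the grid bound", {
  for (seed in 1:5) {
    r <- simulate_clusters(5, points_per_cluster = 100, sigma = 40, seed = seed)
    counts <- bin_localisations(r)
    expect_equal(sum(counts), 500)
    expect_true(all(counts >= 1))
    expect_lte(attr(counts, "n_occupied"), (3000 / 30)^2)
  }
})

test_that("frequency histograms tally occupied-bin counts", {
  expect_equal(frequency_histogram(c(1L, 1L, 2L)),
               tibble::tibble(count = c(1L, 2L), frequency = c(2, 1)))
  expect_equal(frequency_histogram(5L),
               tibble::tibble(count = 5L, frequency = 1))
  expect_equal(nrow(frequency_histogram(integer(0))), 0)
  h <- frequency_histogram(bin_localisations(simulate_csr(900, seed = 3)))
  expect_equal(sum(h$frequency),
               attr(bin_localisations(simulate_csr(900, seed = 3)), "n_occupied"))
})

test_that("empirical CDFs are normalised, support fractional frequencies", {
  e <- empirical_cdf(tibble::tibble(count = c(1L, 2L), frequency = c(2, 1)), 3)
  expect_equal(e$support, c(1L, 2L))
  expect_equal(e$cdf, c(2 / 3, 1))
  single <- empirical_cdf(tibble::tibble(count = 7L, frequency = 1), 1)
  expect_equal(single$cdf, 1)
  # averaged thinned histograms carry fractional frequencies
  frac <- empirical_cdf(tibble::tibble(count = c(1L, 2L),
                                       frequency = c(1.5, 0.5)), 2)
  expect_equal(frac$cdf, c(0.75, 1))
  expect_error(empirical_cdf(tibble::tibble(count = 1L, frequency = 1), 0),
               class = "smlm_empty_roi_error")
})

test_that("the K-S statistic matches hand-worked step-function cases", {
  a <- ecdf_from_counts(c(1, 1, 2, 2))
  expect_equal(ks_statistic(a, a), 0)
  # disjoint supports: all mass at 1 vs all mass at 2
  expect_equal(ks_statistic(ecdf_from_counts(c(1, 1)),
                            ecdf_from_counts(c(2, 2))), 1)
  # A: support (1,2) cdf (.5,1); B: support (1) cdf (1) -> max gap 0.5 at x=1
  expect_equal(ks_statistic(ecdf_from_counts(c(1, 2)),
                            ecdf_from_counts(c(1, 1))), 0.5)
  expect_error(ks_statistic(a, structure(list(support = integer(0),
                                              cdf = numeric(0), sample_size = 0),
                                         class = "ecdf_summary")),
               class = "smlm_empty_roi_error")
})

test_that("the K-S statistic equals the brute-force scan on random histograms", {
  set.seed(2024)
  for (i in 1:300) {
    a <- random_count_ecdf()
    b <- random_count_ecdf()
    expect_equal(ks_statistic(a, b), ks_brute_force(a, b), tolerance = 1e-12)
  }
})

test_that("lambda follows its closed form and threshold semantics", {
  expect_equal(ks_critical_scale(0.05), sqrt(-0.5 * log(0.025)))
  expect_equal(ks_critical_scale(0.05), 1.3581, tolerance = 1e-4)
  expect_error(ks_critical_scale(0), class = "smlm_config_error")
  expect_error(ks_critical_scale(1), class = "smlm_config_error")

  # hand evaluation: m = n = 10, D = 0.5 -> J = 0.2, lambda ~ 0.823
  a <- ecdf_from_counts(rep(c(1, 2), 5))          # support (1,2), cdf (.5, 1)
  b <- ecdf_from_counts(rep(1, 10))               # all mass at 1
  res <- dissimilarity_lambda(a, b)
  expect_equal(res$d_mn, 0.5)
  expect_equal(res$j, 0.2)
  expect_equal(res$lambda, 0.5 / (ks_critical_scale(0.05) * sqrt(0.2)))
  expect_equal(res$lambda, 0.823, tolerance = 1e-3)
  expect_equal(res$lambda, res$d_mn / (res$c_alpha * sqrt(res$j)))

  # identical ROIs score exactly zero
  r <- simulate_clusters(10, points_per_cluster = 90, seed = 11)
  expect_identical(dissimilarity_lambda(r, r)$lambda, 0)

  # symmetry, non-negativity, D in [0,1], threshold iff semantics
  set.seed(31)
  for (i in 1:50) {
    a <- random_count_ecdf()
    b <- random_count_ecdf()
    ra <- dissimilarity_lambda(a, b)
    rb <- dissimilarity_lambda(b, a)
    expect_equal(ra$lambda, rb$lambda)
    expect_gte(ra$lambda, 0)
    expect_true(ra$d_mn >= 0 && ra$d_mn <= 1)
    expect_identical(ra$lambda > 1, ra$d_mn > ra$c_alpha * sqrt(ra$j))
  }
})

test_that("condition-level dissimilarity aggregates the right pair sets", {
  a <- ecdf_from_counts(c(1, 2, 3))
  # identical single-ROI conditions: one cross pair, lambda 0
  cmp <- condition_dissimilarity(list(a), list(a))
  expect_equal(cmp$lambda_bar, 0)
  expect_equal(cmp$n_pairs, 1L)
  # self-comparison of 3 ROIs: 3 unordered distinct pairs
  rois <- purrr::map(1:3, ~ roi_ecdf(simulate_csr(900, seed = .x)))
  expect_equal(condition_dissimilarity(rois)$n_pairs, 3L)
  expect_error(condition_dissimilarity(rois[1]), class = "smlm_config_error")
  # mean of pairwise lambdas; population-sd convention
  lam <- pairwise_lambda(rois)
  expect_equal(condition_dissimilarity(rois)$lambda_bar, mean(lam))
  expect_equal(condition_dissimilarity(rois)$lambda_sd,
               sqrt(mean((lam - mean(lam))^2)))
  # cross-condition pair count is the full bipartite product
  other <- purrr::map(4:5, ~ roi_ecdf(simulate_csr(900, seed = .x)))
  expect_equal(condition_dissimilarity(rois, other)$n_pairs, 6L)
})

test_that("ranking sorts ascending with lexicographic tie-breaks", {
  base <- ecdf_from_counts(rep(1, 20))
  near <- ecdf_from_counts(c(rep(1, 18), 2, 2))
  mid <- ecdf_from_counts(c(rep(1, 10), rep(2, 10)))
  far <- ecdf_from_counts(rep(3, 20))
  ranked <- rank_conditions(list(base), list(C = list(far), B = list(near),
                                             D = list(mid)))
  expect_equal(ranked$condition, c("B", "D", "C"))
  expect_true(!is.unsorted(ranked$lambda_bar))

  # a catalogue copy of the reference ranks first with lambda_bar 0
  ref <- list(base, base)
  ranked2 <- rank_conditions(ref, list(copy = ref, far = list(far)))
  expect_equal(ranked2$condition[1], "copy")
  expect_equal(ranked2$lambda_bar[1], 0)

  # exact ties fall back to lexicographic order of identifiers
  ranked3 <- rank_conditions(list(base), list(zeta = list(near),
                                              beta = list(near)))
  expect_equal(ranked3$condition, c("beta", "zeta"))
  expect_equal(nrow(rank_conditions(list(base), list())), 0)
})
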
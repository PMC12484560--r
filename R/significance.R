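#' Pairwise dissimilarity distance matrix for two groups of ROIs
#'
#' Computes lambda for every pair among the pooled ROIs of a reference and a
#' comparison group, yielding the symmetric zero-diagonal distance matrix on
#' which the permutation test operates.
#'
#' @param ecdfs_a,ecdfs_b Lists of `ecdf_summary` objects (or anything
#'   [as_ecdf_summary()] accepts), one per ROI of each group.
#' @param alpha Significance level for the lambda scale.
#' @param labels Optional length-2 character of group names (default
#'   `c("A", "B")`).
#' @return A symmetric numeric matrix of class `lambda_dist` with a `groups`
#'   attribute (factor of group membership per row/column).
#' @export
build_distance_matrix <- function(ecdfs_a, ecdfs_b, alpha = 0.05,
                                  labels = c("A", "B")) {
  stopifnot(length(labels) == 2)
  all_e <- c(purrr::map(ecdfs_a, as_ecdf_summary),
             purrr::map(ecdfs_b, as_ecdf_summary))
  n <- length(all_e)
  if (length(ecdfs_a) == 0 || length(ecdfs_b) == 0) {
    abort("both groups must contain at least one ROI", class = "smlm_config_error")
  }
  c_alpha <- ks_critical_scale(alpha)
  dm <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      dm[i, j] <- dm[j, i] <- lambda_value(all_e[[i]], all_e[[j]], c_alpha)
    }
  }
  groups <- factor(rep(labels, c(length(ecdfs_a), length(ecdfs_b))),
                   levels = labels)
  dimnames(dm) <- list(paste0(groups, "_", seq_len(n)),
                       paste0(groups, "_", seq_len(n)))
  structure(dm, class = c("lambda_dist", "matrix", "array"), groups = groups)
}

#' Group-separation statistic on a distance matrix
#'
#' The default statistic is the difference between the mean inter-group and
#' mean intra-group distances: positive values indicate that ROIs are closer
#' to their own group than to the other. A PERMANOVA-style pseudo-F
#' (between-group over within-group mean squared distance) is available as
#' an alternative. Groups with fewer than two members simply contribute no
#' intra-group pairs; two singleton groups have no intra-group pairs at all
#' and raise an error.
#'
#' @param dm Symmetric distance matrix (e.g. from [build_distance_matrix()]).
#' @param labels Group labels per row; defaults to the matrix's `groups`
#'   attribute.
#' @param statistic `"mean_diff"` (default) or `"pseudo_f"`.
#' @return Scalar statistic; larger means greater group separation.
#' @export
group_separation_statistic <- function(dm, labels = attr(dm, "groups"),
                                       statistic = c("mean_diff", "pseudo_f")) {
  statistic <- match.arg(statistic)
  lab <- as.character(labels)
  stopifnot(length(lab) == nrow(dm), length(unique(lab)) == 2)
  same <- outer(lab, lab, "==")
  upper <- upper.tri(dm)
  intra <- dm[upper & same]
  inter <- dm[upper & !same]
  if (length(intra) == 0) {
    abort("no intra-group pairs: both groups are singletons",
          class = "smlm_config_error")
  }
  if (statistic == "mean_diff") {
    mean(inter) - mean(intra)
  } else {
    # PERMANOVA-style pseudo-F on squared distances from the pooled matrix
    n <- nrow(dm)
    a <- 2L
    sst <- sum(dm[upper]^2) / n
    ssw <- sum(purrr::map_dbl(unique(lab), function(g) {
      idx <- lab == g
      sub <- dm[idx, idx, drop = FALSE]
      sum(sub[upper.tri(sub)]^2) / sum(idx)
    }))
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
}

#' Monte Carlo permutation test for condition separation
#'
#' Tests whether the dissimilarity between two groups of ROIs exceeds the
#' within-group variability. Group labels are randomly reassigned
#' (preserving group sizes) `n_permutations` times; the p-value is the
#' add-one proportion of permuted statistics at least as large as the
#' observed one, `p = (1 + #\{null >= observed\}) / (1 + n_permutations)`,
#' which is never exactly zero.
#'
#' @inheritParams group_separation_statistic
#' @param n_permutations Number of label permutations (default 1000).
#' @param seed Seed for the permutation stream.
#' @return An object of class `smlm_perm_test`: list with
#'   `observed_statistic`, `null_statistics`, `p_value`, `n_permutations`,
#'   `statistic`, `seed`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
permutation_test <- function(dm, labels = attr(dm, "groups"),
                             n_permutations = 1000, seed = NULL,
                             statistic = c("mean_diff", "pseudo_f")) {
  statistic <- match.arg(statistic)
  if (n_permutations < 1) {
    abort("n_permutations must be >= 1", class = "smlm_config_error")
  }
  labels <- as.factor(labels)
  observed <- group_separation_statistic(dm, labels, statistic)
  nulls <- with_seed_maybe(seed, {
    vapply(seq_len(n_permutations), function(i) {
      group_separation_statistic(dm, sample(labels), statistic)
    }, numeric(1))
  })
  structure(
    list(observed_statistic = observed, null_statistics = nulls,
         p_value = (1 + sum(nulls >= observed)) / (1 + n_permutations),
         n_permutations = n_permutations, statistic = statistic, seed = seed),
    class = "smlm_perm_test"
  )
}

#' @export
print.smlm_perm_test <- function(x, ...) {
  cat("Permutation test on dissimilarity distance matrix\n")
  cat("  statistic (", x$statistic, "): ", signif(x$observed_statistic, 5),
      "\n", sep = "")
  cat("  permutations:", x$n_permutations, "\n")
  cat("  p-value:", signif(x$p_value, 5), "\n")
  invisible(x)
}

#' @export
tidy.smlm_perm_test <- function(x, ...) {
  tibble(statistic = x$observed_statistic, p.value = x$p_value,
         method = paste0("permutation (", x$statistic, ")"),
         n_permutations = x$n_permutations)
}

#' @export
glance.smlm_perm_test <- function(x, ...) {
  tibble(statistic = x$observed_statistic, p.value = x$p_value,
         n_permutations = x$n_permutations,
         null_mean = mean(x$null_statistics),
         null_sd = stats::sd(x$null_statistics))
}

#' Calibrate the permutation test p-values by simulation
#'
#' Repeats the whole test (generate two groups, build the distance matrix,
#' permute) many times and collects the p-values. Under a null generator
#' (both groups drawn from the same condition) the p-value distribution
#' should be close to uniform — its ECDF close to the diagonal — while under
#' a genuine alternative it should concentrate near zero.
#'
#' @param generate_groups Function `function(seed)` returning a list with
#'   elements `a` and `b`: lists of [roi()] objects (or `ecdf_summary`s) for
#'   the two groups.
#' @param calibration_repeats Number of repeats (default 500).
#' @param n_permutations Permutations per repeat (default 1000).
#' @param alpha Lambda scale significance level.
#' @param seed Base seed; each repeat derives its own stream.
#' @param statistic Passed to [permutation_test()].
#' @return A tibble of class `pvalue_calibration` with columns `repeat_index`
#'   and `p_value`.
#' @export
calibrate_pvalues <- function(generate_groups, calibration_repeats = 500,
                              n_permutations = 1000, alpha = 0.05,
                              seed = NULL, statistic = "mean_diff") {
  ps <- purrr::map_dbl(seq_len(calibration_repeats), function(i) {
    gseed <- derive_seed(seed %||% 0, "calibration", i)
    groups <- generate_groups(gseed)
    dm <- build_distance_matrix(groups$a, groups$b, alpha = alpha)
    permutation_test(dm, n_permutations = n_permutations,
                     seed = derive_seed(gseed, "perm"),
                     statistic = statistic)$p_value
  })
  out <- tibble(repeat_index = seq_len(calibration_repeats), p_value = ps)
  structure(out, class = c("pvalue_calibration", class(out)))
}

#' Sup-distance of a p-value sample from the uniform distribution
#'
#' Kolmogorov-style sup distance between the empirical CDF of the collected
#' p-values and the uniform CDF on `[0, 1]`, used to judge calibration.
#'
#' @param calibration A `pvalue_calibration` tibble (or numeric p-values).
#' @return Scalar sup-distance.
#' @export
calibration_sup_distance <- function(calibration) {
  p <- if (is.numeric(calibration)) calibration else calibration$p_value
  p <- sort(p)
  n <- length(p)
  i <- seq_len(n)
  max(pmax(abs(i / n - p), abs((i - 1) / n - p)))
}
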
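#' Bin ROI localisations on a square grid
#'
#' Divides the ROI into `bin_side` x `bin_side` nm bins (30 nm by default —
#' chosen to match typical SMLM localisation precision, giving a 100 x 100
#' grid for a 3 x 3 micrometre ROI) and counts localisations per bin by
#' half-open floor division. Empty bins are excluded: the result is the
#' multiset of counts over *occupied* bins, whose size is the sample size of
#' the Kolmogorov-Smirnov comparison.
#'
#' @param r An [roi()] object.
#' @param bin_side Bin side in nm; must divide the ROI side exactly.
#' @return An integer vector of occupied-bin counts (class `bin_counts`) with
#'   attributes `n_occupied`, `bin_side`, `roi_side`.
#' @export
bin_localisations <- function(r, bin_side = 30) {
  side <- roi_side(r)
  n_per_axis <- side / bin_side
  if (abs(n_per_axis - round(n_per_axis)) > 1e-9) {
    abort(paste0("bin_side (", bin_side, " nm) must divide the ROI side (",
                 side, " nm) exactly"),
          class = "smlm_config_error")
  }
  n_per_axis <- as.integer(round(n_per_axis))
  if (nrow(r) == 0) {
    return(structure(integer(0), class = "bin_counts", n_occupied = 0L,
                     bin_side = bin_side, roi_side = side))
  }
  ix <- floor(r$x / bin_side)
  iy <- floor(r$y / bin_side)
  idx <- ix * n_per_axis + iy
  counts <- as.integer(table(idx))
  structure(counts, class = "bin_counts", n_occupied = length(counts),
            bin_side = bin_side, roi_side = side)
}

#' Frequency histogram of occupied-bin counts
#'
#' @param counts A `bin_counts` vector from [bin_localisations()], or any
#'   integer vector of per-bin localisation counts.
#' @return A tibble with columns `count` (distinct localisations-per-bin
#'   values, ascending) and `frequency` (number of bins with that count);
#'   frequencies sum to the number of occupied bins.
#' @export
frequency_histogram <- function(counts) {
  if (length(counts) == 0) {
    return(tibble(count = integer(0), frequency = numeric(0)))
  }
  tab <- table(as.integer(counts))
  tibble(count = as.integer(names(tab)), frequency = as.numeric(tab))
}

#' Empirical CDF of a count-frequency histogram
#'
#' Builds the empirical cumulative distribution function of the occupied-bin
#' count distribution, the summary on which ROI pairs are compared.
#' Frequencies may be fractional (averaged histograms from thinning), and the
#' sample size may correspondingly be non-integer.
#'
#' @param hist Tibble with columns `count` and `frequency` (frequencies must
#'   sum to `sample_size`).
#' @param sample_size Number of occupied bins (m or n in the two-sample
#'   statistic); must be > 0.
#' @return An object of class `ecdf_summary`: list with `support` (sorted
#'   distinct counts), `cdf` (non-decreasing, ending at 1) and `sample_size`.
#' @export
empirical_cdf <- function(hist, sample_size = sum(hist$frequency)) {
  if (sample_size <= 0) {
    abort("sample_size must be > 0 (empty ROI has no occupied bins)",
          class = "smlm_empty_roi_error")
  }
  ord <- order(hist$count)
  support <- hist$count[ord]
  cdf <- cumsum(hist$frequency[ord]) / sample_size
  structure(list(support = support, cdf = cdf, sample_size = sample_size),
            class = "ecdf_summary")
}

#' @rdname empirical_cdf
#' @param x An object to convert to an `ecdf_summary`.
#' @param ... Passed to methods.
#' @export
as_ecdf_summary <- function(x, ...) UseMethod("as_ecdf_summary")

#' @export
as_ecdf_summary.ecdf_summary <- function(x, ...) x

#' @export
as_ecdf_summary.bin_counts <- function(x, ...) {
  empirical_cdf(frequency_histogram(x), attr(x, "n_occupied"))
}

#' @export
as_ecdf_summary.smlm_roi <- function(x, bin_side = 30, ...) {
  as_ecdf_summary(bin_localisations(x, bin_side = bin_side))
}

#' Summarise an ROI as an occupied-bin count ECDF
#'
#' Convenience wrapper: bin, histogram, ECDF in one step.
#'
#' @param r An [roi()] object.
#' @param bin_side Bin side in nm (default 30).
#' @return An `ecdf_summary`.
#' @export
roi_ecdf <- function(r, bin_side = 30) {
  as_ecdf_summary(r, bin_side = bin_side)
}

# Evaluate a right-continuous step CDF at points x.
eval_step_cdf <- function(e, x) {
  idx <- findInterval(x, e$support)
  c(0, e$cdf)[idx + 1L]
}

#' Two-sample Kolmogorov-Smirnov statistic between count ECDFs
#'
#' `D_mn = max_x |F(x) - G(x)|`, with both empirical CDFs evaluated as
#' right-continuous step functions. The maximum over all real x is attained
#' on the union of the two supports, which is where it is computed.
#'
#' @param a,b `ecdf_summary` objects (or anything [as_ecdf_summary()] accepts).
#' @return The statistic, a scalar in `[0, 1]`.
#' @export
ks_statistic <- function(a, b) {
  a <- as_ecdf_summary(a)
  b <- as_ecdf_summary(b)
  if (length(a$support) == 0 || length(b$support) == 0) {
    abort("cannot compare an empty ROI (no occupied bins)",
          class = "smlm_empty_roi_error")
  }
  xs <- sort(unique(c(a$support, b$support)))
  max(abs(eval_step_cdf(a, xs) - eval_step_cdf(b, xs)))
}

#' Critical value scale for the two-sample K-S test
#'
#' `c(alpha) = sqrt(-0.5 * ln(alpha / 2))`; at the conventional alpha = 0.05
#' this is about 1.3581.
#'
#' @param alpha Significance level in (0, 1).
#' @return Scalar `c(alpha)`.
#' @export
ks_critical_scale <- function(alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) {
    abort("alpha must lie in (0, 1)", class = "smlm_config_error")
  }
  sqrt(-0.5 * log(alpha / 2))
}

#' Dissimilarity score between two ROIs
#'
#' The dissimilarity score lambda is the two-sample K-S statistic between the
#' occupied-bin count ECDFs, scaled by its alpha-level critical value:
#' `lambda = D_mn / (c(alpha) * sqrt(J))` with `J = (n + m) / (n m)` and
#' `c(alpha) = sqrt(-0.5 ln(alpha/2))`. `lambda = 0` means the two ROIs have
#' identical count distributions; `lambda > 1` means they differ
#' significantly at level alpha (the rejection condition
#' `D_mn > c(alpha) sqrt(J)`); values below 1 still rank similarity. The
#' score is symmetric in its arguments and, through J, comparable across
#' sample sizes.
#'
#' @param a,b `ecdf_summary` objects, [roi()] objects, or thinned histograms.
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble: `d_mn`, `j`, `c_alpha`, `alpha`, `lambda`.
#' @examples
#' r <- simulate_clusters(n_clusters = 10, points_per_cluster = 90, seed = 1)
#' dissimilarity_lambda(r, r)$lambda # identical ROIs score 0
#' @export
dissimilarity_lambda <- function(a, b, alpha = 0.05) {
  a <- as_ecdf_summary(a)
  b <- as_ecdf_summary(b)
  c_alpha <- ks_critical_scale(alpha)
  m <- a$sample_size
  n <- b$sample_size
  stopifnot(m > 0, n > 0)
  d <- ks_statistic(a, b)
  j <- (n + m) / (n * m)
  tibble(d_mn = d, j = j, c_alpha = c_alpha, alpha = alpha,
         lambda = d / (c_alpha * sqrt(j)))
}

# Fast scalar lambda for inner loops (no tibble construction).
lambda_value <- function(a, b, c_alpha) {
  d <- ks_statistic(a, b)
  j <- (b$sample_size + a$sample_size) / (b$sample_size * a$sample_size)
  d / (c_alpha * sqrt(j))
}

#' Pairwise dissimilarities between two sets of ROI summaries
#'
#' For distinct conditions every (a, b) pair across the two lists is scored;
#' for a self-comparison (`b` missing, or the same content as `a`) only
#' distinct unordered pairs are used, excluding each ROI against itself, so
#' the self-dissimilarity summarises between-ROI variability rather than
#' trivially including zeros.
#'
#' @param ecdfs_a,ecdfs_b Lists of `ecdf_summary` objects (or objects
#'   coercible by [as_ecdf_summary()]). Omit `ecdfs_b` for a self-comparison.
#' @param alpha Significance level.
#' @return A numeric vector of lambda values, one per pair.
#' @export
pairwise_lambda <- function(ecdfs_a, ecdfs_b = NULL, alpha = 0.05) {
  a <- purrr::map(ecdfs_a, as_ecdf_summary)
  c_alpha <- ks_critical_scale(alpha)
  if (is.null(ecdfs_b)) {
    if (length(a) < 2) {
      abort("self-comparison needs at least 2 ROIs", class = "smlm_config_error")
    }
    pairs <- utils::combn(length(a), 2)
    return(purrr::map_dbl(seq_len(ncol(pairs)), function(k) {
      lambda_value(a[[pairs[1, k]]], a[[pairs[2, k]]], c_alpha)
    }))
  }
  b <- purrr::map(ecdfs_b, as_ecdf_summary)
  as.vector(vapply(b, function(eb) {
    vapply(a, function(ea) lambda_value(ea, eb, c_alpha), numeric(1))
  }, numeric(length(a))))
}

#' Condition-level mean dissimilarity
#'
#' Summarises all pairwise lambda values between two conditions (or within
#' one) as a mean and standard deviation — the condition-level dissimilarity
#' reported when ranking datasets. The standard deviation uses the population
#' (divide-by-N) convention.
#'
#' @inheritParams pairwise_lambda
#' @param thinned Flag recorded in the output: were the inputs thinned
#'   histograms?
#' @return A one-row tibble: `lambda_bar`, `lambda_sd`, `n_pairs`, `thinned`.
#' @export
condition_dissimilarity <- function(ecdfs_a, ecdfs_b = NULL, alpha = 0.05,
                                    thinned = FALSE) {
  lam <- pairwise_lambda(ecdfs_a, ecdfs_b, alpha = alpha)
  tibble(lambda_bar = mean(lam), lambda_sd = sd_pop(lam),
         n_pairs = length(lam), thinned = thinned)
}

condition_content_hash <- function(ecdfs) {
  rlang::hash(purrr::map(ecdfs, function(e) {
    e <- as_ecdf_summary(e)
    list(e$support, e$cdf, e$sample_size)
  }))
}

#' Rank catalogue conditions by similarity to a reference
#'
#' Scores every catalogue condition against the reference condition and
#' returns them ordered by ascending mean dissimilarity (most similar
#' first), ties broken lexicographically by condition identifier. A
#' catalogue entry whose content is identical to the reference is scored as
#' a self-comparison (distinct unordered ROI pairs).
#'
#' @param reference List of `ecdf_summary` objects (one per reference ROI).
#' @param catalogue Named list; each element a list of `ecdf_summary` objects
#'   for one condition.
#' @param alpha Significance level.
#' @param thinned Flag recorded in the output.
#' @return A tibble of class `ranked_conditions` with columns `condition`,
#'   `lambda_bar`, `lambda_sd`, `n_pairs`, `thinned`, sorted ascending by
#'   `lambda_bar`.
#' @export
rank_conditions <- function(reference, catalogue, alpha = 0.05, thinned = FALSE) {
  if (length(catalogue) == 0) {
    out <- tibble(condition = character(0), lambda_bar = numeric(0),
                  lambda_sd = numeric(0), n_pairs = integer(0),
                  thinned = logical(0))
    return(structure(out, class = c("ranked_conditions", class(out))))
  }
  stopifnot(!is.null(names(catalogue)), all(nzchar(names(catalogue))))
  ref_hash <- condition_content_hash(reference)
  rows <- purrr::imap(catalogue, function(ecdfs, id) {
    self <- identical(condition_content_hash(ecdfs), ref_hash)
    cmp <- if (self) {
      condition_dissimilarity(reference, alpha = alpha, thinned = thinned)
    } else {
      condition_dissimilarity(reference, ecdfs, alpha = alpha, thinned = thinned)
    }
    dplyr::mutate(cmp, condition = id, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$lambda_bar, .data$condition)
  structure(out, class = c("ranked_conditions", class(out)))
}
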
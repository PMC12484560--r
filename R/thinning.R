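#' Thin an ROI to a standard localisation density
#'
#' Dissimilarity scores are influenced by localisation density: sparser
#' datasets tend to score as more similar. To compare conditions
#' independently of expression level or acquisition length, each ROI is
#' randomly subsampled (without replacement) to a standard density — 100
#' localisations per square micrometre by default, 900 points for a 3 x 3
#' micrometre ROI — `repeats` times (default 100), a count histogram is
#' built for each subsample, and the histograms are averaged element-wise.
#' ROIs with density strictly below the target are excluded to avoid biasing
#' comparisons (an ROI exactly at the target is retained; its subsample is
#' the full set).
#'
#' Each repeat draws from an RNG stream derived from `(seed, roi_id, repeat)`,
#' so results are reproducible and independent of the order in which ROIs are
#' processed.
#'
#' @param r An [roi()] object.
#' @param target_density Target density in localisations per um^2 (default 100).
#' @param repeats Number of random subsamples to average (default 100).
#' @param bin_side Bin side in nm (default 30).
#' @param seed Base seed for the subsampling streams.
#' @param roi_id Identifier mixed into the per-repeat streams (defaults to a
#'   content hash of the ROI coordinates).
#' @return A `thinned_histogram`: tibble with columns `count` and
#'   `mean_frequency`, attributes `mean_occupied` (mean occupied-bin count
#'   across repeats), `roi_id`, `target_density`, `repeats`, `seed`; or a
#'   `thinning_exclusion` object when the ROI is below the target density.
#' @export
thin_roi <- function(r, target_density = 100, repeats = 100, bin_side = 30,
                     seed = 1L, roi_id = NULL) {
  stopifnot(target_density > 0, repeats >= 1)
  roi_id <- roi_id %||% rlang::hash(list(r$x, r$y))
  dens <- roi_density(r)
  if (dens < target_density) {
    return(structure(list(roi_id = roi_id, density = dens,
                          target_density = target_density),
                     class = "thinning_exclusion"))
  }
  n <- nrow(r)
  k <- as.integer(round(target_density * roi_area_um2(r)))  # round half to even
  side <- roi_side(r)
  n_per_axis <- as.integer(round(side / bin_side))
  ix_all <- floor(r$x / bin_side) * n_per_axis + floor(r$y / bin_side)

  freq_acc <- numeric(k)  # counts per bin cannot exceed the subsample size
  occ_acc <- 0
  for (rep_i in seq_len(repeats)) {
    sel <- if (k == n) seq_len(n) else {
      with_seed_maybe(derive_seed(seed, roi_id, rep_i), sample.int(n, k))
    }
    counts <- table(ix_all[sel])
    tab <- tabulate(as.integer(counts), nbins = k)
    freq_acc <- freq_acc + tab
    occ_acc <- occ_acc + length(counts)
  }
  mean_freq <- freq_acc / repeats
  keep <- which(mean_freq > 0)
  out <- tibble(count = keep, mean_frequency = mean_freq[keep])
  structure(out, class = c("thinned_histogram", class(tibble())),
            mean_occupied = occ_acc / repeats, roi_id = roi_id,
            target_density = target_density, repeats = repeats, seed = seed)
}

#' @rdname thin_roi
#' @param x An object.
#' @export
is_thinning_exclusion <- function(x) inherits(x, "thinning_exclusion")

#' @export
as_ecdf_summary.thinned_histogram <- function(x, ...) {
  empirical_cdf(tibble(count = x$count, frequency = x$mean_frequency),
                sample_size = attr(x, "mean_occupied"))
}

#' @export
as_ecdf_summary.thinning_exclusion <- function(x, ...) {
  abort(paste0("ROI '", x$roi_id, "' was excluded from thinning (density ",
               signif(x$density, 4), " < target ", x$target_density,
               " localisations/um^2)"),
        class = "smlm_thinning_exclusion_error")
}

#' Dissimilarity between thinned histograms
#'
#' Builds count ECDFs from the averaged histograms (using the mean
#' occupied-bin count as the K-S sample size, a real number) and applies the
#' lambda score. Excluded ROIs raise an error.
#'
#' @param a,b `thinned_histogram` objects from [thin_roi()].
#' @param alpha Significance level.
#' @return A one-row tibble as in [dissimilarity_lambda()].
#' @export
thinned_dissimilarity <- function(a, b, alpha = 0.05) {
  if (is_thinning_exclusion(a)) as_ecdf_summary(a)
  if (is_thinning_exclusion(b)) as_ecdf_summary(b)
  dissimilarity_lambda(as_ecdf_summary(a), as_ecdf_summary(b), alpha = alpha)
}

#' Thin every ROI of a condition
#'
#' @param rois List of [roi()] objects.
#' @param ... Passed to [thin_roi()].
#' @return A list with `histograms` (thinned histograms for retained ROIs,
#'   names preserved) and `excluded` (a tibble of excluded ROI ids and their
#'   densities).
#' @export
thin_condition <- function(rois, ...) {
  ids <- names(rois) %||% as.character(seq_along(rois))
  res <- purrr::map2(rois, ids, function(r, id) thin_roi(r, roi_id = id, ...))
  excl <- purrr::keep(res, is_thinning_exclusion)
  list(
    histograms = setNames(purrr::discard(res, is_thinning_exclusion),
                          ids[!purrr::map_lgl(res, is_thinning_exclusion)]),
    excluded = tibble(
      roi_id = purrr::map_chr(excl, "roi_id"),
      density = purrr::map_dbl(excl, "density"),
      target_density = purrr::map_dbl(excl, "target_density")
    )
  )
}
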
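#' Plot an ROI point pattern
#'
#' @param object An [roi()] object.
#' @param point_size Point size passed to [ggplot2::geom_point()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.smlm_roi <- function(object, point_size = 0.3, ...) {
  side <- roi_side(object)
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = point_size, alpha = 0.6) +
    ggplot2::coord_fixed(xlim = c(0, side), ylim = c(0, side), expand = FALSE) +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}

#' Plot a ranked similarity list
#'
#' Conditions ordered by mean dissimilarity to the reference (most similar
#' at the top), with population-SD error bars.
#'
#' @param object A `ranked_conditions` tibble from [rank_conditions()] or
#'   [rank_catalogue()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.ranked_conditions <- function(object, ...) {
  df <- as_tibble(object)
  df$condition <- factor(df$condition, levels = rev(df$condition))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda_bar, y = .data$condition)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = pmax(.data$lambda_bar - .data$lambda_sd, 0),
                   xmax = .data$lambda_bar + .data$lambda_sd),
      height = 0.25
    ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = expression(bar(lambda)), y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a permutation-test null distribution
#'
#' Histogram of permuted group-separation statistics with the observed value
#' marked.
#'
#' @param object An `smlm_perm_test` from [permutation_test()].
#' @param bins Histogram bin count.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.smlm_perm_test <- function(object, bins = 30, ...) {
  ggplot2::ggplot(tibble(statistic = object$null_statistics),
                  ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed_statistic,
                        colour = "red", linewidth = 0.8) +
    ggplot2::labs(x = "group-separation statistic (null)", y = "count",
                  subtitle = paste0("p = ", signif(object$p_value, 3))) +
    ggplot2::theme_minimal()
}

#' Plot a p-value calibration ECDF
#'
#' Empirical CDF of calibration p-values against the uniform diagonal; a
#' well-calibrated null tracks the diagonal.
#'
#' @param object A `pvalue_calibration` tibble from [calibrate_pvalues()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.pvalue_calibration <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$p_value)) +
    ggplot2::stat_ecdf() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1), expand = FALSE) +
    ggplot2::labs(x = "p-value", y = "ECDF") +
    ggplot2::theme_minimal()
}
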
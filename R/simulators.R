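#' Simulate Gaussian nanoclusters in an ROI
#'
#' Places `n_clusters` cluster centres uniformly at random in the ROI and
#' draws each cluster's localisations as isotropic 2-D Gaussian deviates
#' (standard deviation `sigma` per axis) about its centre. Deviates landing
#' outside the ROI are resampled until inside, so the configured total point
#' count is emitted exactly — a requirement for constant-total validation
#' designs. Specify either `points_per_cluster` or `total_points`; an uneven
#' split of `total_points` allocates the remainder round-robin over the
#' first clusters.
#'
#' @param n_clusters Number of clusters (>= 1).
#' @param points_per_cluster Localisations per cluster.
#' @param total_points Alternative to `points_per_cluster`: total
#'   localisations, split (near-)equally over clusters.
#' @param sigma Cluster spread (Gaussian standard deviation per axis) in nm.
#' @param roi_side ROI side in nm (default 3000).
#' @param seed Seed for reproducibility; identical configurations and seeds
#'   give bitwise-identical coordinates.
#' @param cell_label Optional label stored on the ROI.
#' @return An [roi()] object with attribute `sim_config` echoing the
#'   configuration.
#' @export
simulate_clusters <- function(n_clusters, points_per_cluster = NULL,
                              total_points = NULL, sigma = 50,
                              roi_side = 3000, seed = NULL,
                              cell_label = NA_character_) {
  stopifnot(n_clusters >= 1, sigma >= 0, roi_side > 0)
  if (is.null(points_per_cluster) == is.null(total_points)) {
    abort("specify exactly one of points_per_cluster or total_points",
          class = "smlm_config_error")
  }
  per <- if (!is.null(points_per_cluster)) {
    rep(as.integer(points_per_cluster), n_clusters)
  } else {
    base <- rep(total_points %/% n_clusters, n_clusters)
    extra <- total_points %% n_clusters
    base[seq_len(extra)] <- base[seq_len(extra)] + 1L
    base
  }
  pts <- with_seed_maybe(seed, {
    cx <- runif(n_clusters, 0, roi_side)
    cy <- runif(n_clusters, 0, roi_side)
    x <- rep(cx, per) + rnorm(sum(per), 0, sigma)
    y <- rep(cy, per) + rnorm(sum(per), 0, sigma)
    resample_outside(x, y, rep(cx, per), rep(cy, per), sigma, roi_side)
  })
  r <- roi(pts, side = roi_side, cell_label = cell_label)
  attr(r, "sim_config") <- list(kind = "clusters", n_clusters = n_clusters,
                                points_per_cluster = per, sigma = sigma,
                                roi_side = roi_side, seed = seed)
  r
}

# Redraw Gaussian deviates for points outside [0, roi_side)^2 about their
# own cluster centre until every point is inside.
resample_outside <- function(x, y, cx, cy, sigma, roi_side) {
  repeat {
    bad <- which(x < 0 | x >= roi_side | y < 0 | y >= roi_side)
    if (length(bad) == 0) break
    x[bad] <- cx[bad] + rnorm(length(bad), 0, sigma)
    y[bad] <- cy[bad] + rnorm(length(bad), 0, sigma)
  }
  tibble(x = x, y = y)
}

#' Simulate fibrous (filament-like) localisation patterns
#'
#' Each fibre is the chord of a straight line clipped to the ROI square —
#' randomly oriented, or all parallel at `parallel_angle`. Localisations are
#' placed along the chord, uniformly at random by default or evenly spaced
#' with `spacing = "even"`, with optional perpendicular Gaussian jitter to
#' emulate localisation precision. Jittered points falling outside the ROI
#' are redrawn so the configured count is exact.
#'
#' @param n_fibres Number of fibres (>= 1).
#' @param points_per_fibre Localisations per fibre.
#' @param orientation `"random"` (each fibre gets an independent uniform
#'   angle) or `"parallel"`.
#' @param parallel_angle Fibre angle in radians when `orientation =
#'   "parallel"` (0 = horizontal).
#' @param jitter_sigma Perpendicular Gaussian jitter in nm (default 0:
#'   perfectly collinear fibres).
#' @param spacing `"uniform"` (random positions along the chord) or `"even"`.
#' @param roi_side ROI side in nm.
#' @param seed Seed for reproducibility.
#' @param cell_label Optional ROI label.
#' @return An [roi()] object with a `sim_config` attribute.
#' @export
simulate_fibres <- function(n_fibres, points_per_fibre,
                            orientation = c("random", "parallel"),
                            parallel_angle = 0, jitter_sigma = 0,
                            spacing = c("uniform", "even"),
                            roi_side = 3000, seed = NULL,
                            cell_label = NA_character_) {
  orientation <- match.arg(orientation)
  spacing <- match.arg(spacing)
  stopifnot(n_fibres >= 1, points_per_fibre >= 1, jitter_sigma >= 0)
  hi <- roi_side * (1 - 1e-12)  # keep the closed chord inside the half-open ROI
  pts <- with_seed_maybe(seed, {
    out <- purrr::map(seq_len(n_fibres), function(i) {
      ang <- if (orientation == "random") runif(1, 0, pi) else parallel_angle
      ax <- runif(1, 0, roi_side)
      ay <- runif(1, 0, roi_side)
      ch <- clip_line_to_square(ax, ay, cos(ang), sin(ang), 0, hi)
      t <- if (spacing == "uniform") {
        runif(points_per_fibre, ch[1], ch[2])
      } else {
        seq(ch[1], ch[2], length.out = points_per_fibre)
      }
      x <- ax + t * cos(ang)
      y <- ay + t * sin(ang)
      if (jitter_sigma > 0) {
        # redraw the jitter of out-of-ROI points until all land inside,
        # keeping each point's position along the chord fixed
        xj <- x; yj <- y
        need <- rep(TRUE, points_per_fibre)
        while (any(need)) {
          j <- rnorm(sum(need), 0, jitter_sigma)
          cand_x <- x[need] - j * sin(ang)
          cand_y <- y[need] + j * cos(ang)
          ok <- cand_x >= 0 & cand_x < roi_side & cand_y >= 0 & cand_y < roi_side
          idx <- which(need)[ok]
          xj[idx] <- cand_x[ok]
          yj[idx] <- cand_y[ok]
          need[which(need)[ok]] <- FALSE
        }
        x <- xj; y <- yj
      }
      tibble(x = pmin(pmax(x, 0), hi), y = pmin(pmax(y, 0), hi))
    })
    dplyr::bind_rows(out)
  })
  r <- roi(pts, side = roi_side, cell_label = cell_label)
  attr(r, "sim_config") <- list(kind = "fibres", n_fibres = n_fibres,
                                points_per_fibre = points_per_fibre,
                                orientation = orientation,
                                parallel_angle = parallel_angle,
                                jitter_sigma = jitter_sigma,
                                spacing = spacing, roi_side = roi_side,
                                seed = seed)
  r
}

# Parameter range [t0, t1] for which (ax + t dx, ay + t dy) stays inside
# [lo, hi]^2 (Liang-Barsky on an axis-aligned square).
clip_line_to_square <- function(ax, ay, dx, dy, lo, hi) {
  t0 <- -Inf; t1 <- Inf
  for (d in list(c(dx, ax), c(dy, ay))) {
    if (abs(d[1]) < 1e-15) next
    ta <- (lo - d[2]) / d[1]
    tb <- (hi - d[2]) / d[1]
    t0 <- max(t0, min(ta, tb))
    t1 <- min(t1, max(ta, tb))
  }
  c(t0, t1)
}

#' Simulate complete spatial randomness (CSR)
#'
#' Draws `n_points` i.i.d. uniform points in the ROI — the homogeneous
#' Poisson null model against which clustering is judged.
#'
#' @param n_points Number of points (>= 0).
#' @param roi_side ROI side in nm.
#' @param seed Seed for reproducibility.
#' @param cell_label Optional ROI label.
#' @return An [roi()] object with a `sim_config` attribute.
#' @export
simulate_csr <- function(n_points, roi_side = 3000, seed = NULL,
                         cell_label = NA_character_) {
  stopifnot(n_points >= 0)
  pts <- with_seed_maybe(seed, tibble(x = runif(n_points, 0, roi_side),
                                      y = runif(n_points, 0, roi_side)))
  r <- roi(pts, side = roi_side, cell_label = cell_label)
  attr(r, "sim_config") <- list(kind = "csr", n_points = n_points,
                                roi_side = roi_side, seed = seed)
  r
}

#' Simulate a mixture of clustered, fibrous and random localisations
#'
#' Superimposes any combination of a Gaussian-cluster component, a fibre
#' component and a CSR background in one ROI.
#'
#' @param clusters Optional named list of [simulate_clusters()] arguments
#'   (without `roi_side`/`seed`).
#' @param fibres Optional named list of [simulate_fibres()] arguments.
#' @param csr_points CSR background point count (default 0).
#' @param roi_side ROI side in nm.
#' @param seed Seed; component streams are derived from it.
#' @param cell_label Optional ROI label.
#' @return An [roi()] object with a `sim_config` attribute.
#' @export
simulate_mixture <- function(clusters = NULL, fibres = NULL, csr_points = 0,
                             roi_side = 3000, seed = NULL,
                             cell_label = NA_character_) {
  if (is.null(clusters) && is.null(fibres) && csr_points == 0) {
    abort("at least one mixture component must be present",
          class = "smlm_config_error")
  }
  parts <- list()
  if (!is.null(clusters)) {
    parts$clusters <- do.call(simulate_clusters,
                              c(clusters, list(roi_side = roi_side,
                                               seed = derive_seed(seed %||% 0, "clusters"))))
  }
  if (!is.null(fibres)) {
    parts$fibres <- do.call(simulate_fibres,
                            c(fibres, list(roi_side = roi_side,
                                           seed = derive_seed(seed %||% 0, "fibres"))))
  }
  if (csr_points > 0) {
    parts$csr <- simulate_csr(csr_points, roi_side = roi_side,
                              seed = derive_seed(seed %||% 0, "csr"))
  }
  pts <- dplyr::bind_rows(purrr::map(parts, as_tibble))
  r <- roi(pts[, c("x", "y")], side = roi_side, cell_label = cell_label)
  attr(r, "sim_config") <- list(kind = "mixture", clusters = clusters,
                                fibres = fibres, csr_points = csr_points,
                                roi_side = roi_side, seed = seed)
  r
}

#' Simulate a condition: a set of independent ROIs
#'
#' Generates `n_rois` independent ROIs from a generator function, optionally
#' varying generator parameters per ROI to emulate heterogeneous conditions
#' (e.g. cluster counts varying between cells, or two distinct
#' subpopulations). Each ROI gets its own RNG stream derived from `seed`, so
#' the set is reproducible and order-independent.
#'
#' @param n_rois Number of ROIs (>= 1).
#' @param generator A function `function(seed, ...)` returning an [roi()],
#'   e.g. a wrapper around [simulate_clusters()].
#' @param seed Base seed.
#' @param heterogeneity Optional function `function(i)` returning a named
#'   list of extra generator arguments for ROI `i`; called under its own
#'   derived RNG stream so samplers may use randomness.
#' @return A tibble with one row per ROI: `roi_index`, `params` (list column
#'   echoing per-ROI arguments) and `roi` (list column of [roi()] objects).
#' @examples
#' cond <- simulate_condition(3, function(seed, n_clusters = 10)
#'   simulate_clusters(n_clusters, total_points = 900, seed = seed), seed = 1)
#' @export
simulate_condition <- function(n_rois, generator, seed = NULL,
                               heterogeneity = NULL) {
  stopifnot(n_rois >= 1, is.function(generator))
  rows <- purrr::map(seq_len(n_rois), function(i) {
    params <- if (is.null(heterogeneity)) list() else {
      with_seed_maybe(derive_seed(seed %||% 0, "params", i), heterogeneity(i))
    }
    r <- do.call(generator, c(list(seed = derive_seed(seed %||% 0, "roi", i)),
                              params))
    tibble(roi_index = i, params = list(params), roi = list(r))
  })
  dplyr::bind_rows(rows)
}
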
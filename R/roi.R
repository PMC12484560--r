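#' Construct a region of interest (ROI)
#'
#' An ROI is a square tile of localisations — by convention 3 x 3 micrometres
#' (side 3000 nm) — with point coordinates expressed relative to its
#' lower-left corner. ROIs are the unit of comparison for the dissimilarity
#' score. Membership is half-open: `0 <= coordinate < side` on both axes.
#'
#' @param points Tibble (or data frame) with numeric columns `x`, `y` in nm,
#'   relative to the ROI origin; extra columns (e.g. `precision`) are kept.
#' @param side ROI side length in nm (default 3000).
#' @param origin Length-2 numeric, the absolute lower-left corner in nm.
#' @param cell_label Label of the parent cell, if any.
#' @return A tibble of class `smlm_roi` with attributes `side`, `origin`,
#'   `cell_label`.
#' @export
roi <- function(points, side = 3000, origin = c(0, 0), cell_label = NA_character_) {
  pts <- as_tibble(points)
  if (nrow(pts) > 0) {
    stopifnot(all(c("x", "y") %in% names(pts)))
    if (any(pts$x < 0 | pts$x >= side | pts$y < 0 | pts$y >= side)) {
      abort("ROI points must satisfy 0 <= coordinate < side on both axes",
            class = "smlm_geometry_error")
    }
  } else if (!"x" %in% names(pts)) {
    pts <- tibble(x = numeric(0), y = numeric(0))
  }
  stopifnot(side > 0)
  structure(pts,
            class = c("smlm_roi", class(tibble())),
            side = side, origin = as.numeric(origin), cell_label = cell_label)
}

#' @rdname roi
#' @param x An object.
#' @export
is_roi <- function(x) inherits(x, "smlm_roi")

#' ROI geometry helpers
#'
#' `roi_side()` returns the side length in nm, `roi_area_um2()` the area in
#' square micrometres, and `roi_density()` the localisation density in
#' localisations per square micrometre.
#'
#' @param r An [roi()] object.
#' @return A scalar numeric.
#' @export
roi_side <- function(r) attr(r, "side")

#' @rdname roi_side
#' @export
roi_area_um2 <- function(r) (roi_side(r) / 1000)^2

#' @rdname roi_side
#' @export
roi_density <- function(r) nrow(r) / roi_area_um2(r)

boundary_vertices <- function(boundary) {
  if (is_tibble(boundary) && "vertices" %in% names(boundary)) {
    if (nrow(boundary) != 1) {
      abort("expected a single boundary row; subset the boundaries tibble first",
            class = "smlm_geometry_error")
    }
    list(verts = boundary$vertices[[1L]], label = boundary$label[[1L]])
  } else {
    list(verts = as_tibble(boundary), label = "cell")
  }
}

#' Tile a cell into standardised ROIs
#'
#' Lays a regular square grid over the cell and cuts the localisation table
#' into ROIs. The grid is anchored at the lower-left corner of the boundary
#' polygon's bounding box, so tiling is reproducible per cell and invariant
#' to joint translation of points and boundary. Only localisations inside the
#' boundary polygon are assigned; each falls in at most one tile via
#' half-open membership. Tiles whose fractional overlap with the polygon is
#' below `min_coverage` are dropped — the default keeps only fully interior
#' tiles, since the dissimilarity score assumes a full square support.
#'
#' @param locs Localisation tibble (absolute nm coordinates).
#' @param boundary A one-row boundary tibble ([cell_boundary()]) or a tibble
#'   of vertices `x`, `y`.
#' @param side Tile side in nm (default 3000).
#' @param min_coverage Minimum fraction of tile area inside the polygon for a
#'   tile to be kept, in (0, 1] (default 1: fully interior tiles only).
#' @return A tibble with one row per retained ROI: `cell_label`, `row`,
#'   `col`, `origin_x`, `origin_y`, `side`, `n_points`, `density`
#'   (localisations per um^2), `coverage`, and a list column `roi` of
#'   [roi()] objects.
#' @export
tile_rois <- function(locs, boundary, side = 3000, min_coverage = 1) {
  stopifnot(side > 0, min_coverage > 0, min_coverage <= 1)
  b <- boundary_vertices(boundary)
  validate_polygon(b$verts, b$label)
  vx <- b$verts$x
  vy <- b$verts$y
  if (abs(polygon_area(vx, vy)) < .Machine$double.eps) {
    abort(paste0("boundary '", b$label, "' has zero area"),
          class = "smlm_geometry_error")
  }
  x0 <- min(vx); y0 <- min(vy)
  ncol_t <- max(1L, ceiling((max(vx) - x0) / side))
  nrow_t <- max(1L, ceiling((max(vy) - y0) / side))

  grid <- tidyr::expand_grid(row = seq_len(nrow_t) - 1L, col = seq_len(ncol_t) - 1L)
  grid$origin_x <- x0 + grid$col * side
  grid$origin_y <- y0 + grid$row * side
  grid$coverage <- purrr::map2_dbl(grid$origin_x, grid$origin_y, function(ox, oy) {
    clip_area(vx, vy, ox, oy, ox + side, oy + side) / side^2
  })
  grid <- grid[grid$coverage >= min_coverage - 1e-9, , drop = FALSE]
  if (nrow(grid) == 0) return(empty_roi_tiles())

  pts <- as_tibble(locs)
  if (nrow(pts) > 0) {
    inside <- mgcv::in.out(as.matrix(rbind(b$verts[, c("x", "y")],
                                           b$verts[1L, c("x", "y")])),
                           as.matrix(pts[, c("x", "y")]))
    pts <- pts[inside, , drop = FALSE]
  }
  col_idx <- floor((pts$x - x0) / side)
  row_idx <- floor((pts$y - y0) / side)

  rois <- purrr::pmap(grid, function(row, col, origin_x, origin_y, coverage) {
    sel <- which(row_idx == row & col_idx == col)
    sub <- pts[sel, , drop = FALSE]
    sub$x <- sub$x - origin_x
    sub$y <- sub$y - origin_y
    roi(sub, side = side, origin = c(origin_x, origin_y), cell_label = b$label)
  })
  tibble(cell_label = b$label, row = grid$row, col = grid$col,
         origin_x = grid$origin_x, origin_y = grid$origin_y, side = side,
         n_points = purrr::map_int(rois, nrow),
         density = purrr::map_dbl(rois, roi_density),
         coverage = grid$coverage,
         roi = rois)
}

empty_roi_tiles <- function() {
  tibble(cell_label = character(0), row = integer(0), col = integer(0),
         origin_x = numeric(0), origin_y = numeric(0), side = numeric(0),
         n_points = integer(0), density = numeric(0), coverage = numeric(0),
         roi = list())
}

#' Assess ROI density and coverage
#'
#' @param r An [roi()] object (tiled from `boundary`).
#' @param boundary The cell boundary the ROI was tiled from.
#' @return A one-row tibble with `density` (localisations per um^2) and
#'   `coverage` (fraction of ROI area inside the polygon, in `[0, 1]`).
#' @export
assess_quality <- function(r, boundary) {
  b <- boundary_vertices(boundary)
  side <- roi_side(r)
  o <- attr(r, "origin")
  cov <- clip_area(b$verts$x, b$verts$y, o[1], o[2], o[1] + side, o[2] + side) / side^2
  tibble(density = roi_density(r), coverage = min(max(cov, 0), 1))
}

# Shoelace signed area of a polygon given open vertex lists.
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

# Area of polygon intersected with the axis-aligned rectangle
# [xmin,xmax] x [ymin,ymax] via Sutherland-Hodgman clipping (the clip window
# is convex; degenerate edges introduced for concave subjects lie on the
# window boundary and carry zero area).
clip_area <- function(px, py, xmin, ymin, xmax, ymax) {
  poly <- list(x = px, y = py)
  poly <- clip_halfplane(poly, function(x, y) x >= xmin,
                         function(x1, y1, x2, y2) {
                           t <- (xmin - x1) / (x2 - x1); c(xmin, y1 + t * (y2 - y1))
                         })
  poly <- clip_halfplane(poly, function(x, y) x <= xmax,
                         function(x1, y1, x2, y2) {
                           t <- (xmax - x1) / (x2 - x1); c(xmax, y1 + t * (y2 - y1))
                         })
  poly <- clip_halfplane(poly, function(x, y) y >= ymin,
                         function(x1, y1, x2, y2) {
                           t <- (ymin - y1) / (y2 - y1); c(x1 + t * (x2 - x1), ymin)
                         })
  poly <- clip_halfplane(poly, function(x, y) y <= ymax,
                         function(x1, y1, x2, y2) {
                           t <- (ymax - y1) / (y2 - y1); c(x1 + t * (x2 - x1), ymax)
                         })
  if (length(poly$x) < 3) return(0)
  abs(polygon_area(poly$x, poly$y))
}

clip_halfplane <- function(poly, inside, intersect) {
  n <- length(poly$x)
  if (n == 0) return(poly)
  ox <- numeric(0); oy <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- poly$x[i]; y1 <- poly$y[i]
    x2 <- poly$x[j]; y2 <- poly$y[j]
    in1 <- inside(x1, y1); in2 <- inside(x2, y2)
    if (in1) {
      ox <- c(ox, x1); oy <- c(oy, y1)
      if (!in2) { p <- intersect(x1, y1, x2, y2); ox <- c(ox, p[1]); oy <- c(oy, p[2]) }
    } else if (in2) {
      p <- intersect(x1, y1, x2, y2); ox <- c(ox, p[1]); oy <- c(oy, p[2])
    }
  }
  list(x = ox, y = oy)
}
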
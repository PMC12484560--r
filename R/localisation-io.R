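#' Read a localisation table
#'
#' Reads a table of single-molecule localisations from CSV or HDF5 and
#' returns a tibble with coordinates in nanometres. Three CSV dialects are
#' supported: `"thunderstorm"` (headers `"x [nm]"`, `"y [nm]"`, optionally
#' `"uncertainty [nm]"` and `"frame"`), `"plain"` (`x,y[,precision][,frame]`,
#' assumed nm), and `"pixel"` (`x,y[,precision]` in camera pixels, requiring
#' `pixel_size`). HDF5 files (`.h5`/`.hdf5`) are expected to hold a single
#' record array with fields `x`, `y` and optionally `precision`/`uncertainty`
#' and `frame` at `dataset` (default `"locs"`, the dominant community layout);
#' the `pixel` dialect applies the same pixel-to-nm conversion there.
#'
#' @param path Path to a `.csv`, `.h5` or `.hdf5` file.
#' @param dialect One of `"auto"`, `"thunderstorm"`, `"plain"`, `"pixel"`.
#'   `"auto"` inspects the header (CSV) or assumes nm fields (HDF5).
#' @param pixel_size Camera pixel size in nm; required for the `"pixel"`
#'   dialect and ignored otherwise.
#' @param dataset HDF5 dataset path holding the localisation record array.
#' @return A tibble with numeric columns `x`, `y` (nm) and, when present in
#'   the input, `precision` (nm) and `frame`; attributes `source_path` and
#'   `unit` (always `"nm"`). Row order is preserved.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("x,y", "100,200", "300,400"), path)
#' read_localisations(path)
#' @export
read_localisations <- function(path,
                               dialect = c("auto", "thunderstorm", "plain", "pixel"),
                               pixel_size = NULL,
                               dataset = "locs") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("localisation file not found: ", path), class = "smlm_io_error")
  }
  is_h5 <- grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)
  raw <- if (is_h5) read_locs_hdf5(path, dataset) else read_locs_csv(path)
  tab <- normalise_loc_columns(raw, dialect, pixel_size, path)
  attr(tab, "source_path") <- path
  attr(tab, "unit") <- "nm"
  tab
}

read_locs_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  as_tibble(df)
}

read_locs_hdf5 <- function(path, dataset) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  ds <- sub("^/", "", file.path(contents$group, contents$name))
  ds <- sub("^/", "", ds)
  if (!dataset %in% ds) {
    abort(paste0("HDF5 dataset '", dataset, "' not found in ", path),
          class = "smlm_format_error")
  }
  rec <- rhdf5::h5read(path, dataset)
  as_tibble(as.data.frame(rec))
}

# Map dialect-specific column names onto the canonical x/y/precision/frame
# schema and convert lengths to nm.
normalise_loc_columns <- function(raw, dialect, pixel_size, path) {
  nms <- names(raw)
  if (dialect == "auto") {
    dialect <- if (any(grepl("^x \\[nm\\]$", nms))) "thunderstorm" else "plain"
  }
  lookup <- switch(dialect,
    thunderstorm = c(x = "x [nm]", y = "y [nm]",
                     precision = "uncertainty [nm]", frame = "frame"),
    plain = c(x = "x", y = "y", precision = "precision", frame = "frame"),
    pixel = c(x = "x", y = "y", precision = "precision", frame = "frame")
  )
  for (req in c("x", "y")) {
    if (!lookup[[req]] %in% nms) {
      abort(paste0("missing coordinate column '", lookup[[req]], "' in ", path),
            class = "smlm_format_error")
    }
  }
  if (dialect == "pixel" && is.null(pixel_size)) {
    abort("dialect 'pixel' requires `pixel_size` (nm per camera pixel)",
          class = "smlm_config_error")
  }
  scale <- if (dialect == "pixel") as.numeric(pixel_size) else 1
  out <- tibble(x = parse_numeric_column(raw[[lookup[["x"]]]], lookup[["x"]]) * scale,
                y = parse_numeric_column(raw[[lookup[["y"]]]], lookup[["y"]]) * scale)
  if (lookup[["precision"]] %in% nms) {
    out$precision <- parse_numeric_column(raw[[lookup[["precision"]]]],
                                          lookup[["precision"]]) * scale
  }
  if (lookup[["frame"]] %in% nms) {
    out$frame <- as.integer(parse_numeric_column(raw[[lookup[["frame"]]]],
                                                 lookup[["frame"]]))
  }
  if (any(!is.finite(out$x)) || any(!is.finite(out$y))) {
    bad <- which(!is.finite(out$x) | !is.finite(out$y))[1L]
    abort(paste0("non-finite coordinate at row ", bad), class = "smlm_parse_error")
  }
  out
}

parse_numeric_column <- function(v, name) {
  if (is.numeric(v)) return(as.numeric(v))
  suppressWarnings(num <- as.numeric(v))
  bad <- which(is.na(num) & !is.na(v) & nzchar(trimws(v)))
  if (length(bad) > 0) {
    abort(paste0("non-numeric value '", v[bad[1L]], "' in column '", name,
                 "' at row ", bad[1L]),
          class = "smlm_parse_error")
  }
  num
}

#' Write a localisation table
#'
#' Writes a localisation tibble (nm coordinates) to plain CSV
#' (`x,y[,precision][,frame]`) or to an HDF5 record array, chosen by the file
#' extension. The written file round-trips through [read_localisations()].
#'
#' @param locs Tibble with columns `x`, `y` and optionally `precision`, `frame`.
#' @param path Output path ending in `.csv`, `.h5` or `.hdf5`.
#' @param dataset HDF5 dataset path (default `"locs"`).
#' @return `path`, invisibly.
#' @export
write_localisations <- function(locs, path, dataset = "locs") {
  keep <- intersect(c("x", "y", "precision", "frame"), names(locs))
  df <- as.data.frame(locs[keep])
  if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(df, path, dataset)
    rhdf5::h5closeAll()
  } else {
    readr::write_csv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' Filter localisations by estimated precision
#'
#' Keeps only localisations whose estimated precision is at or below
#' `max_precision`, the standard quality filter applied before nanoscale
#' organisation analysis (30 nm by convention, matching typical SMLM
#' localisation precision). The filter is optional: tables uploaded already
#' filtered can skip it.
#'
#' @param locs Localisation tibble carrying a `precision` column (nm).
#' @param max_precision Maximum allowed precision in nm (default 30).
#' @return The filtered tibble; row order preserved, attributes retained.
#' @export
filter_precision <- function(locs, max_precision = 30) {
  if (!"precision" %in% names(locs)) {
    abort(paste("table has no 'precision' column;",
                "skip the precision filter for pre-filtered data"),
          class = "smlm_config_error")
  }
  keep <- locs$precision <= max_precision
  out <- locs[keep, , drop = FALSE]
  attr(out, "source_path") <- attr(locs, "source_path")
  attr(out, "unit") <- attr(locs, "unit")
  out
}

#' Construct a cell boundary polygon
#'
#' @param x,y Polygon vertex coordinates in nm, in order; the polygon is
#'   implicitly closed.
#' @param label Cell label.
#' @return A one-row tibble with columns `label` and `vertices` (a list column
#'   holding a tibble of `x`, `y`).
#' @export
cell_boundary <- function(x, y, label = "cell") {
  verts <- tibble(x = as.numeric(x), y = as.numeric(y))
  validate_polygon(verts, label)
  tibble(label = label, vertices = list(verts))
}

validate_polygon <- function(verts, label) {
  if (nrow(verts) < 3) {
    abort(paste0("boundary '", label, "' has fewer than 3 vertices"),
          class = "smlm_geometry_error")
  }
  if (any(!is.finite(verts$x)) || any(!is.finite(verts$y))) {
    abort(paste0("boundary '", label, "' has non-finite vertices"),
          class = "smlm_geometry_error")
  }
  if (polygon_self_intersects(verts$x, verts$y)) {
    abort(paste0("boundary '", label, "' is self-intersecting"),
          class = "smlm_geometry_error")
  }
  invisible(verts)
}

# Test whether any two non-adjacent edges of the closed polygon cross.
polygon_self_intersects <- function(x, y) {
  n <- length(x)
  x2 <- c(x, x[1L]); y2 <- c(y, y[1L])
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    j <- seq.int(i + 2L, jmax)
    if (length(j) == 0) next
    hit <- segments_intersect(x2[i], y2[i], x2[i + 1L], y2[i + 1L],
                              x2[j], y2[j], x2[j + 1L], y2[j + 1L])
    if (any(hit)) return(TRUE)
  }
  FALSE
}

# Vectorised proper-intersection test of segment (ax,ay)-(bx,by) against
# segments (cx,cy)-(dx,dy).
segments_intersect <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  d1 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d2 <- (bx - ax) * (dy - ay) - (by - ay) * (dx - ax)
  d3 <- (dx - cx) * (ay - cy) - (dy - cy) * (ax - cx)
  d4 <- (dx - cx) * (by - cy) - (dy - cy) * (bx - cx)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Read cell boundary polygons
#'
#' Accepts either a two-column CSV (`x,y` vertex list in nm; one polygon,
#' labelled by the file stem) or a JSON object mapping labels to arrays of
#' `[x, y]` vertex pairs (several polygons per file).
#'
#' @param path Path to a `.csv` or `.json` boundary file.
#' @return A tibble with one row per polygon: columns `label` and `vertices`.
#' @export
read_boundaries <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("boundary file not found: ", path), class = "smlm_io_error")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    out <- purrr::imap(obj, function(mat, label) {
      mat <- as.matrix(mat)
      cell_boundary(as.numeric(mat[, 1]), as.numeric(mat[, 2]), label = label)
    })
    return(dplyr::bind_rows(out))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("x", "y") %in% names(df))) {
    abort(paste0("boundary CSV must have columns x,y: ", path),
          class = "smlm_format_error")
  }
  label <- sub("\\.[^.]*$", "", basename(path))
  cell_boundary(df$x, df$y, label = label)
}

#' Write cell boundary polygons
#'
#' @param boundaries Tibble as returned by [cell_boundary()] or
#'   [read_boundaries()].
#' @param path Output `.json` path (multi-polygon, keyed by label).
#' @return `path`, invisibly.
#' @export
write_boundaries <- function(boundaries, path) {
  obj <- setNames(
    purrr::map(boundaries$vertices, ~ unname(as.matrix(.x[, c("x", "y")]))),
    boundaries$label
  )
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

# Controlled vocabulary for the imaging modality; free text is preserved in
# modality_text when it falls outside the vocabulary (e.g. MINFLUX -> other).
smlm_modalities <- c("PALM", "dSTORM", "PAINT", "other")

#' Condition metadata
#'
#' Describes one experimental condition: imaging modality, protein, cell type,
#' fluorophore, optional treatment and DOI, and the post-processing state of
#' the data (drift and multiple-blink correction, mean localisation
#' precision). Modalities outside the fixed vocabulary (PALM, dSTORM, PAINT)
#' are stored as `"other"` with the original text kept in `modality_text`.
#'
#' @param modality Imaging modality; free text, normalised to the vocabulary.
#' @param protein,cell_type,fluorophore Character descriptors.
#' @param treatment,doi Optional character descriptors.
#' @param drift_corrected,blink_corrected Logical post-processing flags.
#' @param mean_precision Optional mean localisation precision in nm (> 0).
#' @return An object of class `condition_metadata` (a named list).
#' @export
condition_metadata <- function(modality, protein, cell_type, fluorophore,
                               treatment = NULL, doi = NULL,
                               drift_corrected = FALSE, blink_corrected = FALSE,
                               mean_precision = NULL) {
  modality_text <- as.character(modality)
  if (!modality_text %in% smlm_modalities) {
    modality <- "other"
  }
  if (!is.null(mean_precision) && mean_precision <= 0) {
    abort("mean_precision must be > 0 nm", class = "smlm_validation_error")
  }
  structure(
    list(modality = as.character(modality), modality_text = modality_text,
         protein = protein, cell_type = cell_type, fluorophore = fluorophore,
         treatment = treatment, doi = doi,
         drift_corrected = isTRUE(drift_corrected),
         blink_corrected = isTRUE(blink_corrected),
         mean_precision = mean_precision),
    class = "condition_metadata"
  )
}

#' Write and read condition metadata
#'
#' Metadata is stored as a JSON sidecar (`metadata.json` by convention inside
#' each condition directory) and round-trips exactly.
#'
#' @param meta A [condition_metadata()] object.
#' @param path JSON file path.
#' @return `write_metadata()` returns `path` invisibly; `read_metadata()`
#'   returns a `condition_metadata` object.
#' @export
write_metadata <- function(meta, path) {
  stopifnot(inherits(meta, "condition_metadata"))
  jsonlite::write_json(unclass(meta), path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("metadata file not found: ", path), class = "smlm_io_error")
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("modality", "protein", "cell_type", "fluorophore",
                "drift_corrected", "blink_corrected")
  missing <- setdiff(required, names(obj))
  if (length(missing) > 0) {
    abort(paste0("metadata missing required field(s): ",
                 paste(missing, collapse = ", ")),
          class = "smlm_validation_error")
  }
  if (!obj$modality %in% smlm_modalities) {
    abort(paste0("unknown modality '", obj$modality, "'; expected one of ",
                 paste(smlm_modalities, collapse = ", ")),
          class = "smlm_validation_error")
  }
  meta <- condition_metadata(
    modality = obj$modality, protein = obj$protein, cell_type = obj$cell_type,
    fluorophore = obj$fluorophore, treatment = obj$treatment, doi = obj$doi,
    drift_corrected = obj$drift_corrected, blink_corrected = obj$blink_corrected,
    mean_precision = obj$mean_precision
  )
  if (!is.null(obj$modality_text)) meta$modality_text <- obj$modality_text
  meta
}
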
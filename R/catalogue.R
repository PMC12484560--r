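#' Write a condition directory
#'
#' Conditions live in a catalogue: one directory per experimental condition
#' holding per-ROI localisation CSVs (`roi_###.csv`, plain `x,y` dialect, nm,
#' coordinates relative to each ROI origin), a `metadata.json` sidecar, and —
#' for simulated conditions — a `ground_truth.json` echo of the generator
#' configuration.
#'
#' @param rois List of [roi()] objects, or a tibble with a `roi` list column
#'   (as produced by [tile_rois()] or [simulate_condition()]).
#' @param dir Condition directory (created if needed).
#' @param metadata Optional [condition_metadata()] sidecar.
#' @param ground_truth Optional list written as `ground_truth.json`.
#' @return `dir`, invisibly.
#' @export
write_condition <- function(rois, dir, metadata = NULL, ground_truth = NULL) {
  if (is.data.frame(rois) && "roi" %in% names(rois)) rois <- rois$roi
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  purrr::iwalk(rois, function(r, i) {
    path <- file.path(dir, sprintf("roi_%03d.csv", as.integer(i)))
    df <- as_tibble(r)[, intersect(c("x", "y", "precision", "frame"), names(r))]
    readr::write_csv(df, path, progress = FALSE)
  })
  sides <- purrr::map_dbl(rois, roi_side)
  jsonlite::write_json(list(side = unique(sides)),
                       file.path(dir, "rois.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(metadata)) write_metadata(metadata, file.path(dir, "metadata.json"))
  if (!is.null(ground_truth)) {
    jsonlite::write_json(ground_truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  invisible(dir)
}

#' Read a condition directory
#'
#' @param dir Condition directory written by [write_condition()].
#' @return A list with `rois` (named list of [roi()] objects), `metadata`
#'   (`condition_metadata` or `NULL`) and `ground_truth` (list or `NULL`).
#' @export
read_condition <- function(dir) {
  files <- sort(list.files(dir, pattern = "^roi_\\d+\\.csv$", full.names = TRUE))
  side <- 3000
  side_file <- file.path(dir, "rois.json")
  if (file.exists(side_file)) {
    side <- jsonlite::read_json(side_file, simplifyVector = TRUE)$side
  }
  rois <- purrr::map(files, function(f) {
    roi(read_localisations(f, dialect = "plain"), side = side,
        cell_label = basename(dir))
  })
  names(rois) <- sub("\\.csv$", "", basename(files))
  meta_file <- file.path(dir, "metadata.json")
  gt_file <- file.path(dir, "ground_truth.json")
  list(rois = rois,
       metadata = if (file.exists(meta_file)) read_metadata(meta_file) else NULL,
       ground_truth = if (file.exists(gt_file)) {
         jsonlite::read_json(gt_file, simplifyVector = TRUE)
       } else NULL)
}

# --- pairwise-lambda cache -------------------------------------------------
#
# Pairwise lambda values are cached keyed by a content hash of the two ROI
# summaries plus the scoring parameters, so re-ranking after new uploads
# recomputes only pairs involving new or modified data.

ecdf_hash <- function(e) {
  e <- as_ecdf_summary(e)
  rlang::hash(list(e$support, e$cdf, e$sample_size))
}

lambda_cache_path <- function(root) file.path(root, ".cache", "lambda_cache.csv")

read_lambda_cache <- function(root) {
  path <- lambda_cache_path(root)
  if (!file.exists(path)) {
    return(tibble(key = character(0), lambda = numeric(0)))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = "cc")
  tibble(key = raw$key, lambda = as.numeric(raw$lambda))
}

write_lambda_cache <- function(cache, root) {
  dir.create(dirname(lambda_cache_path(root)), recursive = TRUE,
             showWarnings = FALSE)
  # 17 significant digits so cached doubles round-trip bit-exactly
  out <- tibble(key = cache$key,
                lambda = formatC(cache$lambda, digits = 17, format = "g"))
  readr::write_csv(out, lambda_cache_path(root), progress = FALSE)
}

pair_key <- function(hash_a, hash_b, alpha, thinned) {
  ordered <- sort(c(hash_a, hash_b))
  paste(ordered[1], ordered[2], alpha, thinned, sep = "|")
}

#' Rank all conditions of a catalogue against a reference condition
#'
#' Reads every condition directory under `root`, summarises each ROI as an
#' occupied-bin count ECDF (after optional thinning), scores all pairwise
#' lambda values against the reference condition, and returns the ranked
#' similarity list. Pairwise scores are cached under `root/.cache/` keyed by
#' content hash, so unchanged pairs are not recomputed on later calls.
#' Conditions whose ROIs are all below the thinning density are reported in
#' the `excluded` attribute rather than ranked.
#'
#' @param root Catalogue root directory (one sub-directory per condition).
#' @param reference Name of the reference condition (a sub-directory of
#'   `root`).
#' @param thinned Apply density thinning before scoring?
#' @param alpha Significance level for the lambda scale.
#' @param bin_side Bin side in nm.
#' @param target_density,repeats Thinning parameters (see [thin_roi()]).
#' @param seed Seed for the thinning streams.
#' @param use_cache Use and update the pairwise-lambda cache?
#' @return A `ranked_conditions` tibble (see [rank_conditions()]) with
#'   attributes `excluded` (character vector of conditions dropped by
#'   thinning) and `cache_hits` (number of pairs served from the cache).
#' @export
rank_catalogue <- function(root, reference, thinned = FALSE, alpha = 0.05,
                           bin_side = 30, target_density = 100, repeats = 100,
                           seed = 1L, use_cache = TRUE) {
  dirs <- list.dirs(root, recursive = FALSE)
  dirs <- dirs[!grepl("^\\.", basename(dirs))]
  if (!reference %in% basename(dirs)) {
    abort(paste0("reference condition '", reference, "' not found in ", root),
          class = "smlm_io_error")
  }
  summaries <- list()
  excluded <- character(0)
  for (d in dirs) {
    cond <- read_condition(d)
    ec <- if (thinned) {
      th <- thin_condition(cond$rois, target_density = target_density,
                           repeats = repeats, bin_side = bin_side, seed = seed)
      purrr::map(th$histograms, as_ecdf_summary)
    } else {
      purrr::map(cond$rois, function(r) roi_ecdf(r, bin_side = bin_side))
    }
    if (length(ec) == 0) {
      excluded <- c(excluded, basename(d))
    } else {
      summaries[[basename(d)]] <- ec
    }
  }
  if (!reference %in% names(summaries)) {
    abort(paste0("reference condition '", reference,
                 "' has no ROIs at the required density"),
          class = "smlm_io_error")
  }
  ref <- summaries[[reference]]
  cache <- if (use_cache) read_lambda_cache(root) else NULL
  hits <- 0L
  new_rows <- list()
  c_alpha <- ks_critical_scale(alpha)
  ref_hashes <- purrr::map_chr(ref, ecdf_hash)

  score_pairs <- function(ecdfs_b, self) {
    b_hashes <- purrr::map_chr(ecdfs_b, ecdf_hash)
    pairs <- if (self) {
      idx <- utils::combn(length(ref), 2)
      tibble(i = idx[1, ], j = idx[2, ])
    } else {
      tidyr::expand_grid(i = seq_along(ref), j = seq_along(ecdfs_b))
    }
    purrr::map2_dbl(pairs$i, pairs$j, function(i, j) {
      key <- pair_key(ref_hashes[i], b_hashes[j], alpha, thinned)
      if (!is.null(cache)) {
        hit <- cache$lambda[cache$key == key]
        if (length(hit) == 1) {
          hits <<- hits + 1L
          return(hit)
        }
      }
      lam <- if (self) {
        lambda_value(ref[[i]], ref[[j]], c_alpha)
      } else {
        lambda_value(ref[[i]], ecdfs_b[[j]], c_alpha)
      }
      new_rows[[length(new_rows) + 1L]] <<- tibble(key = key, lambda = lam)
      lam
    })
  }

  rows <- purrr::imap(summaries, function(ecdfs, id) {
    self <- identical(id, reference) ||
      identical(condition_content_hash(ecdfs), condition_content_hash(ref))
    if (self && length(ref) < 2) {
      abort(paste0("self-comparison of '", id, "' needs at least 2 ROIs"),
            class = "smlm_config_error")
    }
    lam <- score_pairs(ecdfs, self)
    tibble(condition = id, lambda_bar = mean(lam), lambda_sd = sd_pop(lam),
           n_pairs = length(lam), thinned = thinned)
  })
  if (use_cache && length(new_rows) > 0) {
    write_lambda_cache(dplyr::distinct(
      dplyr::bind_rows(c(list(cache), new_rows)), .data$key, .keep_all = TRUE
    ), root)
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$lambda_bar, .data$condition)
  structure(out, class = c("ranked_conditions", class(out)),
            excluded = excluded, cache_hits = hits)
}
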
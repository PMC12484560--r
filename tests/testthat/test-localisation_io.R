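test_that("CSV dialects parse and convert to nm", {
  # ThunderSTORM-style headers
  ts <- tempfile(fileext = ".csv")
  writeLines(c('"x [nm]","y [nm]","uncertainty [nm]"',
               "100,200,10", "300,400,25"), ts)
  tab <- read_localisations(ts)
  expect_equal(tab$x, c(100, 300))
  expect_equal(tab$y, c(200, 400))
  expect_equal(tab$precision, c(10, 25))
  expect_identical(attr(tab, "unit"), "nm")

  # plain dialect, row order preserved
  pl <- tempfile(fileext = ".csv")
  writeLines(c("x,y", "300,400", "100,200"), pl)
  expect_equal(read_localisations(pl)$x, c(300, 100))

  # pixel dialect requires and applies pixel_size
  px <- tempfile(fileext = ".csv")
  writeLines(c("x,y", "1.5,2.0"), px)
  expect_error(read_localisations(px, dialect = "pixel"),
               class = "smlm_config_error")
  tab_px <- read_localisations(px, dialect = "pixel", pixel_size = 100)
  expect_equal(tab_px$x, 150)
  expect_equal(tab_px$y, 200)

  # empty CSV with a valid header is a 0-point table, not an error
  em <- tempfile(fileext = ".csv")
  writeLines("x,y", em)
  expect_equal(nrow(read_localisations(em)), 0)
})

test_that("malformed localisation files fail with informative errors", {
  bad <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), bad)
  expect_error(read_localisations(bad), class = "smlm_format_error",
               regexp = "x")
  nn <- tempfile(fileext = ".csv")
  writeLines(c("x,y", "1,2", "oops,4"), nn)
  expect_error(read_localisations(nn), class = "smlm_parse_error",
               regexp = "row 2")
  expect_error(read_localisations(tempfile(fileext = ".csv")),
               class = "smlm_io_error")
})

test_that("HDF5 record arrays round-trip and honour pixel units", {
  locs <- tibble::tibble(x = c(1.5, 2.0), y = c(2.0, 3.5), precision = c(0.1, 0.2))
  h5 <- tempfile(fileext = ".h5")
  write_localisations(locs, h5)
  back <- read_localisations(h5, dialect = "pixel", pixel_size = 100)
  expect_equal(back$x, c(150, 200))
  expect_equal(back$y, c(200, 350))
  expect_equal(back$precision, c(10, 20))
  expect_error(read_localisations(h5, dataset = "missing"),
               class = "smlm_format_error")
})

test_that("CSV and HDF5 round trips reproduce coordinates to 1e-6 nm", {
  locs <- simulate_csr(200, seed = 42)
  for (ext in c(".csv", ".h5")) {
    path <- tempfile(fileext = ext)
    write_localisations(locs, path)
    back <- read_localisations(path)
    expect_equal(back$x, locs$x, tolerance = 1e-9)
    expect_equal(back$y, locs$y, tolerance = 1e-9)
  }
})

test_that("nm and pixel dialects of the same data agree", {
  locs <- simulate_csr(50, seed = 7)
  nm_path <- tempfile(fileext = ".csv")
  px_path <- tempfile(fileext = ".csv")
  write_localisations(locs, nm_path)
  write_localisations(dplyr::mutate(tibble::as_tibble(locs),
                                    x = x / 117, y = y / 117), px_path)
  a <- read_localisations(nm_path)
  b <- read_localisations(px_path, dialect = "pixel", pixel_size = 117)
  expect_equal(a$x, b$x, tolerance = 1e-9)
  expect_equal(a$y, b$y, tolerance = 1e-9)
})

test_that("precision filter keeps points at or below the threshold", {
  tab <- tibble::tibble(x = 1:4, y = 1:4, precision = c(10, 25, 31, 40))
  kept <- filter_precision(tab, 30)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$precision, c(10, 25))
  # identity when all pass; empty when none; idempotent; order preserved
  expect_equal(filter_precision(tab, 100), tab)
  expect_equal(nrow(filter_precision(tab, 5)), 0)
  expect_equal(filter_precision(kept, 30), kept)
  expect_error(filter_precision(tibble::tibble(x = 1, y = 1), 30),
               class = "smlm_config_error", regexp = "skip")
})

test_that("boundary files parse, validate geometry, and round-trip", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("x,y", "0,0", "6000,0", "6000,6000", "0,6000"), csv)
  b <- read_boundaries(csv)
  expect_equal(nrow(b), 1)
  v <- b$vertices[[1]]
  expect_equal(abs(smlmdissim:::polygon_area(v$x, v$y)), 36e6) # 36 um^2

  two <- tempfile(fileext = ".json")
  write_boundaries(dplyr::bind_rows(
    square_boundary(1000, label = "cellA"),
    square_boundary(2000, x0 = 5000, label = "cellB")
  ), two)
  bb <- read_boundaries(two)
  expect_equal(bb$label, c("cellA", "cellB"))
  expect_equal(nrow(bb$vertices[[2]]), 4)

  expect_error(cell_boundary(c(0, 1), c(0, 1), "short"),
               class = "smlm_geometry_error")
  # bow-tie self-intersection is rejected by name
  expect_error(cell_boundary(c(0, 10, 10, 0), c(0, 10, 0, 10), "bowtie"),
               class = "smlm_geometry_error", regexp = "bowtie")
})

test_that("condition metadata validates and round-trips through JSON", {
  meta <- condition_metadata("dSTORM", protein = "TIGIT", cell_type = "NK",
                             fluorophore = "AF647", treatment = "none",
                             doi = "10.0000/example", drift_corrected = TRUE,
                             blink_corrected = TRUE, mean_precision = 12.5)
  path <- tempfile(fileext = ".json")
  write_metadata(meta, path)
  expect_equal(read_metadata(path), meta)

  # out-of-vocabulary modality maps to "other", original text preserved
  mfx <- condition_metadata("MINFLUX", "p", "c", "f")
  expect_identical(mfx$modality, "other")
  expect_identical(mfx$modality_text, "MINFLUX")
  write_metadata(mfx, path)
  expect_equal(read_metadata(path), mfx)

  # unknown modality or missing fields on read are validation errors
  jsonlite::write_json(list(modality = "EM", protein = "p", cell_type = "c",
                            fluorophore = "f", drift_corrected = FALSE,
                            blink_corrected = FALSE),
                       path, auto_unbox = TRUE)
  expect_error(read_metadata(path), class = "smlm_validation_error")
  jsonlite::write_json(list(modality = "PALM"), path, auto_unbox = TRUE)
  expect_error(read_metadata(path), class = "smlm_validation_error",
               regexp = "protein")
  expect_error(condition_metadata("PALM", "p", "c", "f", mean_precision = -1),
               class = "smlm_validation_error")
})
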
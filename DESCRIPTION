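Package: smlmdissim
Title: Statistical Similarity of Nanoscale Organisation in SMLM Point Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing the nanoscale spatial organisation of proteins
    imaged by single-molecule localisation microscopy (SMLM). Localisation
    tables are tiled into standardised 3x3 micrometre regions of interest,
    binned on a 30 nm grid, and summarised as empirical distribution functions
    of occupied-bin counts. Pairs of regions are scored with a two-sample
    Kolmogorov-Smirnov dissimilarity scaled by its critical value (lambda),
    conditions are ranked by mean dissimilarity, and density differences are
    normalised by repeated random thinning to a standard localisation density.
    Includes point-pattern simulators (Gaussian nanoclusters, fibres, complete
    spatial randomness, mixtures) and a Monte Carlo permutation test on
    dissimilarity distance matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rhdf5,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
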
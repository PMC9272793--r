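Package: spatpal
Title: Spatially Aware Color Palette Assignment for Single-Cell and
    Spatial Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assigns a user-supplied categorical color palette to cell or
    spot clusters in a two-dimensional embedding (UMAP, t-SNE) or spatial
    tissue map so that spatially neighboring clusters receive visually
    distinct colors. Per-cluster spatial footprints are estimated by
    two-dimensional kernel density estimation on a shared grid, a
    permutation-derived density cutoff defines each cluster's hot grid
    points, and the Jaccard overlap between hot sets weights pairwise
    color distances in an objective maximized by random restarts and
    pairwise color exchanges with early stopping. Supports channel-weighted
    RGB distances and color-vision-deficiency simulation so optimized
    palettes remain distinct for viewers with protan, deutan or tritan
    color vision.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    colorspace,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
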
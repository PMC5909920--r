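Package: plantspace
Title: Plant Spacing Estimation from Nadir UAV RGB Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates individual row-crop plants (maize seedlings) in nadir RGB
    images taken from a low-flying UAV and measures the ground-metric interval
    distance between consecutive plants within each planting row. Implements
    excess-green (EXG) vegetation segmentation with Otsu or fixed thresholds,
    area/shape outlier filtering and dilation-based fragment merging,
    perspective correction of canopy centroids to stem positions from camera
    and plant height, iterative buffer-based crop row detection, projection and
    ordering of plants along rows, and pairwise and row-wise accuracy metrics.
    Includes a forward-model scene simulator that renders row-planted scenes
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
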
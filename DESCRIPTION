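Package: ki67cells
Title: Cell Detection and Ki-67/TILs Scoring in IHC Images by Density-Map
    Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies Ki-67 immunopositive tumor cells,
    immunonegative tumor cells and tumor-infiltrating lymphocytes (TILs) in
    immunohistochemistry (IHC) stained breast-cancer microscopy tiles.  Point
    annotations of cell centers are encoded as per-class Gaussian density
    maps; a residual dilated inception encoder-decoder network regresses the
    density maps from RGB tiles; thresholding, a Euclidean distance transform
    and a deterministic priority-flood watershed recover cell-center
    coordinates; radius-matched detection metrics, the Ki-67 proliferation
    index, the TILs score and their clinical cut-off categories complete the
    pipeline.  A seeded synthetic-image generator with exact ground truth
    makes every stage testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
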
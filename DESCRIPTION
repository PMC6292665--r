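Package: standcount
Title: Stand Density Estimation from Spectral Local Maxima in High-Resolution Imagery
Version: 0.1.0
Authors@R: person("standcount", "developers", role = c("aut", "cre"),
    email = "standcount@example.org")
Description: Estimates forest stand density from very-high-resolution optical
    imagery by detecting spectral local maxima (candidate tree tops) with a
    moving-window maximum filter, removing pseudo crown points by NDVI
    thresholding, counting surviving points in field sample plots, selecting
    the optimal band/window-size/NDVI-threshold combination by Pearson
    correlation against field-measured tree counts, calibrating linear and
    quadratic density regressions with leave-one-out cross-validation, and
    mapping stand density on a 20 m fishnet grid. Includes a synthetic forest
    scene generator so the full pipeline is testable without proprietary
    satellite imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
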
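Package: cropgam
Title: Rapid Monitoring of Cropland Productivity with Spatio-Temporal GAMs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes gridded cropland Gross Primary Productivity (GPP) time
    series into seasonal, inter-annual and spatial components with a penalized
    regression spline generalized additive model (cubic and cyclic cubic
    splines, a low-rank Gaussian-process spatial smooth, tensor-product
    interactions), corrects residual temporal dependence with an AR(1) error
    model, and tests for an additive step change in productivity after a
    disruption date via a directly estimated pre/post factor. Includes effect
    curve and prediction surface extraction with uncertainty, bivariate
    tercile uncertainty classes for mapping, validation statistics against
    annual crop production series, port-buffer extraction of shipping
    route-density rasters with cumulative-change summaries, and synthetic data
    generators so the full pipeline is testable without satellite downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    readr,
    rlang,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv,
    geosphere,
    jsonlite
Config/testthat/edition: 3
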
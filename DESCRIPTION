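Package: standgrowth
Title: Forest Stand Height Increments from Two-Epoch Airborne Laser Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates forest-stand height increments from two epochs of
    classified airborne LiDAR point clouds and assesses their agreement with
    field-inventory stand heights. Implements the full processing chain:
    class-based point filtering, Delaunay-TIN rasterization of first/last
    returns into digital surface and terrain models, canopy height model
    differencing, Gaussian smoothing, height masking, variable-window
    local-maxima tree-top detection, cross-epoch matching of forest-unit
    polygons via poles of inaccessibility, occurrence-weighted stand heights,
    height-difference classing with gross-error flagging, and agreement
    statistics (weighted Pearson correlation, bias, RMSE, relative bias,
    Jenks natural-breaks classing, detection precision/recall, and Monte
    Carlo propagation of inventory height uncertainty). A synthetic-forest
    generator emulating pine-dominated stands provides fully reproducible
    two-epoch test scenes so that every stage runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
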
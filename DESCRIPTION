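Package: orchardcanopy
Title: Tree Crown Delineation and Pruning Analysis from Orchard Surface Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Object-based analysis of digital surface models (DSMs) of orchards:
    chessboard segmentation of the DSM into square tiles, height-variability
    classification of tiles into tree and bare-soil objects, pixel-level border
    refinement, and connected-component labeling of individual trees. For every
    delineated tree the package computes projected canopy area, tree height and
    crown volume against a local bare-soil ground reference, assigns plantation
    row/column identity, and quantifies multi-temporal pruning impact, annual
    growth and restoration per tree and per pruning treatment. A synthetic
    orchard simulator with exact analytic ground truth (half-ellipsoid crowns,
    traditional/adapted/mechanical pruning, regrowth) supports validation
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
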
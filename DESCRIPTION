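Package: hazelhealth
Title: Multispectral Vegetation-Index Pipeline for Orchard Tree Health
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of drone-acquired multispectral orchard
    imagery for per-tree health monitoring: canopy segmentation by NDVI
    thresholding with contour-hierarchy filtering, 3x3 slicing of plant
    images for sub-canopy phenotyping, computation of nine vegetation
    indices (NDVI, GNDVI, GCI, NDREI, RECI, NRI, GI, TCARI, SAVI) with
    per-slice aggregation, data-driven index selection by standardised
    class separation, and supervised binary health classification (random
    forest, k-nearest neighbours, penalised logistic regression) with
    false-negative-oriented evaluation. Includes a calibrated synthetic
    multispectral orchard simulator so that every stage is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    class,
    glmnet,
    jsonlite,
    randomForest,
    stats,
    tiff,
    utils,
    withr
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
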
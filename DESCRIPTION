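Package: reef3d
Title: Multi-Modal Coral Reef Segmentation and 3D Structural Change Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fine-grained monitoring of coral reef habitats from
    photogrammetric products. Performs multi-modal (RGB + height) semantic
    segmentation of co-registered orthomosaic and digital surface model (DSM)
    patches with a shape-aware convolutional encoder-decoder network trained
    under a hybrid cross-entropy plus soft-IoU loss, and quantifies structural
    change with DSM differencing, multi-scale vector ruggedness (VRM),
    and multi-scale point-cloud roughness, all stratified by benthic class
    (live coral, dead coral, background) and projectable onto triangle meshes.
    Includes a synthetic two-epoch reef scene generator with known growth and
    mortality for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
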
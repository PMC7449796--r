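Package: hypoxiamap
Title: Ratiometric Hypoxia-Biosensor Quantification in 3D Brain Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of genetically encoded hypoxia-biosensor
    imaging in the developing insect brain. Segments nuclei from a nuclear
    baseline-reporter channel in multi-channel 3D stacks, computes per-nucleus
    GFP-ODD/RFP ratios and their whole-hemisphere normalisation, extracts a
    voxel-resolution tracheal map with skeleton length measurements, computes
    exact 3D Euclidean nucleus-to-tracheole distances, fits a decaying
    exponential oxygenation-versus-distance model with predicted hypoxia
    heatmaps, stratifies results by brain compartment and cell type, and
    applies assumption-gated two-group statistics. Includes a synthetic brain
    phantom generator with full ground truth so every stage of the pipeline is
    testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tiff,
    minpack.lm,
    car,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
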
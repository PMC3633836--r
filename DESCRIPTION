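Package: spherokit
Title: Quantitative Analysis of Multicellular Tumor Spheroid Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for the quantitative assays used to evaluate
    drug formulations in multicellular tumor spheroid (MCTS) cultures:
    automated spheroid volumetry from brightfield micrographs (Otsu
    thresholding, mask extraction, calibrated area and sphere-volume
    conversion), distance-map radial quantification of stained
    cross-sections into periphery/intermediate/core thirds, Gompertz growth
    modelling of volume time series, Hill/IC50 dose-response analysis of
    acid-phosphatase viability plates, clonogenic surviving-fraction
    statistics, and cumulative drug-release summarization. Seeded synthetic
    generators with attached ground truth emulate every input so the whole
    workflow is exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    withr,
    jsonlite,
    tiff,
    png,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
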
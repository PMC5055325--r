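Package: retilayers
Title: Dual-Scale Gradient Segmentation and Sector Thickness Analysis of Macular OCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for high-throughput analysis of macular spectral-domain
    optical coherence tomography (OCT) raster volumes. Implements dual-scale
    gradient edge scoring with exact dynamic-programming tracing of nine
    intraretinal boundaries per B-scan, fovea localization, ETDRS sector-grid
    thickness summaries, the four scan quality-control indices used for cohort
    exclusion (signal strength, ILM indicator, validity count, motion
    indicators), and a fetch-segment-extract-delete batch engine with parallel
    workers and a throughput accounting model. Ships a synthetic phantom
    generator with known boundary geometry, multiplicative gamma speckle, and
    injectable blink, motion and clipping artifacts so the whole pipeline is
    testable without study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    parallel,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
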
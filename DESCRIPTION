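Package: camarsh
Title: CA-Markov Simulation and Zonation Metrics for Coastal Wetland
    Landscape Succession
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying shore-parallel vegetation-zone succession in
    coastal wetlands from time series of categorical landscape rasters.
    Estimates row-stochastic class-transition matrices from dated map pairs,
    annualizes them by matrix roots, and simulates succession with a
    CA-Markov model (Markov area demands allocated spatially by a
    neighbourhood contiguity filter). Includes map-agreement validation
    (confusion matrix, overall accuracy, Cohen's kappa, transition-area
    cross-tabulation), baseline-referenced zonation geometry (mean boundary
    distance L = S/D, centroids, band widths, seaward movement rates), a
    synthetic banded-landscape generator for end-to-end testing, and a
    pipeline orchestrator. Developed around the succession of Phragmites
    australis, Suaeda salsa and mudflat belts in the Yancheng coastal
    natural wetlands and the Spartina alterniflora invasion there.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
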
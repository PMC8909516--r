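Package: ricegru
Title: Detecting Heavy-Metal Stress in Rice from Red-Edge Index Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for detecting stable (heavy-metal-type)
    stress in paddy rice from multitemporal multispectral imagery. Computes
    eight red-edge and broadband vegetation indices per pixel per date, masks
    terrain-implausible pixels by slope and cloud-contaminated observations by
    QA flag, builds fixed-length per-pixel index sequences, classifies them
    with a gated-recurrent-unit (GRU) sequence model implemented from its cell
    equations, and evaluates results with confusion matrices, per-class
    accuracy/precision/recall/F1, user's and producer's accuracies, and
    Cohen's Kappa. A synthetic scene generator emulating rice phenology under
    persistent stress makes the whole pipeline runnable and testable without
    satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tiff,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
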
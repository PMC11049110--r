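Package: holotox
Title: Multimodal Label-Free Cytotoxicity Assessment by Quantitative Phase
    Imaging and Plate-Reader Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing nanoparticle cytotoxicity from digital
    holographic microscopy (DHM) together with downstream biochemical
    plate-reader assays. Reconstructs calibrated quantitative phase maps from
    off-axis hologram stacks (Fourier sideband demodulation, quality-guided
    phase unwrapping, angular-spectrum refocusing with autofocus, stack
    averaging), corrects the phase background with an exact rolling-ball
    (grayscale opening) filter, converts mean phase shift to cell-population
    dry mass and 24 h dry-mass increments, normalizes WST-8 viability and
    kinetic LDH release measurements against plate controls, and fits
    four-parameter logistic dose-response curves with EC50 estimates,
    fit-acceptance rules and control-comparison statistics. A synthetic-data
    module simulates phase scenes with known dry mass, off-axis interferogram
    stacks and absorbance plates, so the entire pipeline is testable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
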
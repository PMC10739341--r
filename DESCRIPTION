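Package: rhizobridge
Title: Image-Based Phenotyping and Stochastic Simulation of Adventitious Root
    System Architecture
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bridges time-series root-image phenotyping and
    functional-structural root modelling for vegetatively propagated
    cuttings. Computes thermal-time metrics (chilling units, forcing units,
    growing degree days) and log-logistic T50 rooting-phenology estimates
    from daily weather and rooting records; extracts RhizoVision-style
    architecture traits (length, area, solidity, diameters, orientation,
    tips, branch points, holes) from binary root masks via skeletonization
    and distance transforms; converts trait summaries into per-root-order
    growth-model parameters through a declarative equation table; simulates
    stochastic 2D/3D root systems with truncated-normal parameter draws,
    best-of-N tropisms, lateral branching and geometric confinement; renders
    simulations back to binary masks; and evaluates simulations against
    observations with k-fold cross-validation, Welch t-tests, Bonferroni
    adjustment and a confusion-matrix sensitivity rate. Ships a synthetic
    fixture generator with analytic ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    xml2,
    EBImage,
    png,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    purrr,
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
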
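Package: ulmphantom
Title: Microvascular Flow Phantom Simulation and Ultrasound Localization
    Microscopy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for super-resolution ultrasound localization microscopy
    (ULM) of microvascular flow phantoms. Builds parametric bifurcating and
    trifurcating rectangular-channel networks with conservation-of-mass flow
    assignment and plane-Poiseuille velocity profiles, simulates microbubble
    transport and renders post-beamformed contrast-pulse-sequence (CPS) or
    B-mode image stacks with ground truth, and implements the ULM processing
    chain: bicubic upsampling, singular-value-decomposition clutter
    filtering, zero-phase temporal high-pass filtering, adaptive peak
    detection, weighted-centroid subpixel localization, minimum-distance
    track linking, displacement velocimetry, super-resolved density and
    velocity maps, and region-of-interest saturation-time statistics with
    exponential fitting and two-sample comparisons.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
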
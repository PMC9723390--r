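Package: nlobone
Title: Quantitative Analysis of Multimodal Nonlinear Optical Images of Bone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying bone composition and collagen architecture
    from co-registered multimodal nonlinear optical microscopy images
    (second-harmonic generation, two-photon excited fluorescence, and
    stimulated Raman scattering). Computes region-of-interest intensity
    statistics for collagen content, pixel-wise collagen fibre orientation
    from Sobel gradients with percentage orientation histograms, fits of a
    baseline-plus-Gaussian orientation model with an alignment-ratio summary,
    bone versus bone-marrow lipid and protein composition ratios, and group
    comparisons with exact Mann-Whitney U and t tests. Includes a seeded
    synthetic vertebra-scene generator with known ground truth (fibre
    orientation mixtures, cos^4 polarization response, compartment intensity
    contrasts) so the full pipeline is testable without raw microscope data,
    plus multipage TIFF input/output and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    grDevices,
    png,
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
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
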
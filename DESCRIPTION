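Package: veinflow
Title: Venous Reflux Quantification and Classification from Phase-Contrast
    MRI Flow Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative flow (QFlow) analysis of cine through-plane
    velocity maps of the lower-extremity veins and classification of limbs
    with superficial venous reflux. Provides a seeded synthetic cine
    generator with closed-form ground-truth hemodynamics, computation of the
    eight per-ROI flow parameters (stroke volume, forward and backward flow
    volume, regurgitant fraction, absolute stroke volume, mean flux, stroke
    distance, mean velocity), assembly of the six-feature classifier input,
    a radial basis function neural network trained with k-means center
    placement and normalized least-mean-squares output weights, confusion
    matrix performance metrics, and per-segment group comparisons by
    Student's t test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
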
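Package: gaitlrp
Title: Subject Identification from Gait Curves with Layer-Wise Relevance
    Propagation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies individuals from multichannel gait time series
    (ground reaction forces and sagittal-plane joint angles) with a family
    of linear and neural network models, and decomposes every prediction
    into per-input relevance values via Layer-Wise Relevance Propagation
    (LRP). Includes a synthetic gait generator with controllable between-
    and within-subject variability, the standard biomechanical
    preprocessing chain (zero-phase Butterworth filtering, stride
    segmentation by force-plate threshold, body-weight normalization,
    101-point time normalization, z-transform and min-max scaling),
    subject-stratified ten-fold cross-validation with mini-batch SGD
    training, random-order perturbation robustness summarised as the area
    over the perturbation curve (AOPC), and a coefficient-of-variation
    measure of explanation reliability across trials and splits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
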
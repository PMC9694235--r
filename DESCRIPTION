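Package: zoomnn
Title: Zoom-In Neural Networks for Resting-State fMRI ROI Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Backpropagation-free feedforward deep learning built from
    zoom-in learning units (ZLUs) over a neuro-fuzzy base learner with
    weighted fuzzy membership functions (NEWFM), together with a
    resting-state fMRI region-of-interest (ROI) feature pipeline: Haar
    wavelet coefficients of ROI time series, graph-theoretic measures of
    inter-ROI functional connectivity, per-ROI feature and region
    selection, and hold-out evaluation of one-vs-rest disease assessments
    (AD, MCI, NC). Includes a synthetic cohort generator with
    class-dependent spectral content and inter-ROI correlation so the
    whole pipeline is exercisable without access-restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
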
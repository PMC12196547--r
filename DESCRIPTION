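Package: gaitscreen
Title: Dual-View Gait-Video Screening for Parkinson's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end screening of Parkinson's disease from dual-view
    (frontal + lateral) 2-D skeletal keypoint sequences extracted from gait
    video. Provides single-step segmentation of walking recordings via
    Savitzky-Golay smoothing and sliding-window minima selection, scale and
    length normalization of segmented steps, a two-stream sequence classifier
    that alternates self-attention and state-space (Mamba-2 style) blocks with
    per-layer cross-attention fusion, a composite training objective combining
    class-weighted cross-entropy with a maximum mean discrepancy (MMD)
    regularizer and L1/L2 penalties, subject-grouped k-fold evaluation with
    best-F1 checkpointing, an optional physiological-prior adjustment head,
    and a synthetic dual-view gait generator with known step boundaries for
    validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
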
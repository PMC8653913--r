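Package: edapeaks
Title: Peak Detection and Feature Construction for Ambulatory Electrodermal Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for processing ambulatory wrist-sensor electrodermal
    activity (EDA) recordings: task segmentation, FIR low-pass filtering,
    near-zero (loose-connection) invalid-sample handling, per-task min-max
    normalization, two smoothing methods (penalized B-spline regression with
    GCV-selected roughness penalty, and local polynomial regression with
    autoregressive errors estimated by a difference-based method with
    BIC-selected order), derivative-based skin-conductance-response peak
    identification with drop thresholds, and per-profile peak features
    (counts, times to first/highest peak, amplitudes, reactivity, AUC).
    Includes a deterministic synthetic EDA simulator with known ground truth
    (tonic drift, bi-exponential phasic events, AR noise, motion-artifact
    spikes, loose-connection dropout) for validation, plus a batch pipeline
    and command-line interface.
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
    KernSmooth,
    purrr,
    readr,
    rlang,
    signal,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
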
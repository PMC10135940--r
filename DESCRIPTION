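Package: ppgbp
Title: Cuff-Less Blood Pressure Estimation from Photoplethysmograms with a
    Multi-Scale Attention Residual Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for continuous, cuff-less estimation of
    systolic and diastolic blood pressure from the photoplethysmogram (PPG).
    Includes a synthetic paired PPG/arterial-pressure waveform simulator with
    controllable blood pressure, heart rate and noise; signal conditioning
    (zero-phase Butterworth band-pass filtering, fixed-window segmentation,
    skewness and autocorrelation signal-quality screening, min-max
    normalization, velocity and acceleration plethysmogram channels); a one
    dimensional residual regression network with a multi-scale convolutional
    stem and squeeze-and-excitation channel attention, trained with the Huber
    loss under SGD and cosine-annealed learning rates; and standards-based
    evaluation (AAMI error limits, BHS cumulative-error grading, Bland-Altman
    agreement, correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
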
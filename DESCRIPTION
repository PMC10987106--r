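Package: pulsegram
Title: Vital Signs and Cuffless Blood Pressure from Wearable ECG and PPG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing and modelling toolkit for sternal wearable
    cardiovascular monitors. Derives heart rate, heart-rate variability
    (SDNN), ECG-derived respiration rate, dual-wavelength pulse-oximetry
    SpO2, signal-to-noise ratio and signal-quality gating from ECG/PPG
    sessions; implements a calibration-free blood-pressure pipeline that
    bandpass-filters photoplethysmograms, cuts them into labelled 10-second
    segments, renders Morlet continuous-wavelet-transform scalogram images,
    and regresses systolic/diastolic pressure with a residual convolutional
    network evaluated against the AAMI 5 +/- 8 mmHg criterion; and provides
    the group-comparison statistics used in remote-monitoring studies
    (Welch's t, Levene's test, Games-Howell pairwise testing with a compact
    letter display). Includes seeded synthetic-waveform generators with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
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
    Rcpp,
    RcppArmadillo
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
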
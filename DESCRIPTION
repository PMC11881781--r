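Package: pupildrift
Title: Pupillometry Pipeline Linking Reflexive Pupil Dilation to Illusory
    Motion Duration
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for event-locked pupillometry of the
    peripheral-drift (illusory motion) paradigm. Preprocesses 500 Hz pupil
    diameter and gaze traces (windowed median/MAD outlier rejection and
    moving-average smoothing), segments trials by stimulus onset, blink
    (zero-run detection) or saccade (horizontal gaze-step detection),
    extracts the constriction/dilation profile (three extremum points and
    four derived measures), converts pupil diameter to area-based retinal
    luminance change and Troland values, and relates per-trial measures to
    reported illusion durations via Pearson correlations with default
    Bayes factors. Includes a synthetic eye-tracking data generator with
    exact ground truth so the full pipeline is testable without recorded
    data, and a luminance-modulation demo that mimics the retinal effect
    of a pupil response on a static image.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
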
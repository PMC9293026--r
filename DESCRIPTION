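Package: erpreliab
Title: Automated Low-Density ERP Pipeline and Reliability Analysis for
    Developmental EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated analysis toolbox for event-related EEG recorded
    from low-density (8-channel) arrays in infants and toddlers.  Implements
    epoch segmentation with zero-phase Butterworth band-pass and DFT line-noise
    filtering, amplitude/flat-signal artifact flagging with trial-wise fallback
    re-referencing, a sample-wise peak-identification algorithm with plateau
    handling and window widening, extraction of P1/N290/P400 latency and
    amplitude features, a dynamic-time-warping latency statistic (signed
    warping-path area), gaze-based trial validity scoring, and ICC(3,1)
    test-retest and split-half reliability analysis across trial counts.
    Includes a synthetic-session simulator with known ground truth so the
    whole chain is verifiable without access to infant EEG recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
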
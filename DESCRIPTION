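Package: erpmicro
Title: ERP Microstate and Distributed Source Analysis for Two-Group EEG Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end electrical-neuroimaging pipeline for two-group
    event-related potential (ERP) studies: sensor-space preprocessing
    (zero-phase Butterworth band-pass, power-line notch, decimation,
    threshold artifact rejection, baseline correction, average reference,
    spherical-spline channel interpolation), Global Field Power statistics,
    topographic microstate segmentation by modified k-means with
    cross-validation and Krzanowski-Lai model selection and subject-level
    back-fitting, a three-shell spherical head model with analytic lead
    fields, depth-weighted minimum-norm distributed source imaging,
    cluster-extent corrected statistical parametric mapping with Monte
    Carlo calibration of the extent threshold, and closed-form behavioral
    statistics (d-prime, exact binomial classification, summary-statistic
    t and chi-squared tests).  A synthetic-data module generates two-group,
    three-condition epoched EEG with a planted early-latency source
    difference so that the whole pipeline can be exercised and validated
    without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
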
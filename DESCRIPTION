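Package: mspilot
Title: EEG Microstate Analysis for Simulator-Based Training Protocols
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end EEG microstate analysis of repeated-session training
    protocols: band-pass filtering and artifact cleaning with channel and
    epoch criteria, spherical-spline interpolation, global field power peak
    selection, polarity-invariant modified k-means microstate clustering
    with a predictive cross-validation criterion, full-permutation group
    aggregation with canonical A-G labelling, smoothing-free backfitting
    with coverage, occurrence and duration parameters, entropy-rate and
    detrended-fluctuation-analysis Hurst measures of microstate sequence
    dynamics, Welch theta-band powers over five cortical areas, and balanced
    repeated-measures ANOVA with Greenhouse-Geisser correction. Includes a
    synthetic-data generator with planted topographies and label sequences
    of known entropy rate and Hurst exponent, so every stage of the pipeline
    can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    tools,
    utils,
    withr
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
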
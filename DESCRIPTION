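Package: asmespeller
Title: Simulation and Decoding Toolkit for a 30-Class Auditory
    Stream-Segregation ERP Speller
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end desk-scale simulation of an auditory brain-computer
    interface speller in which the 26 letters and four symbols of a QWERTY
    keyboard are mapped to three pitch-segregated auditory streams.  Provides
    the 30-class stimulus paradigm (pseudorandomised schedules for trials,
    runs and sessions), a configurable synthetic-EEG generator with
    target-locked ERP components (N2, P300, N700), a steady-state stimulus
    response and 1/f background noise, causal Butterworth preprocessing and
    interval-mean feature extraction, per-stimulus decoders (Ledoit-Wolf
    shrinkage LDA, xDAWN spatial filtering, and xDAWN-covariance Riemannian
    tangent-space classification), trial-level letter decisions with static
    and dynamic (one-sided Welch t-test) stopping rules, and the standard
    speller performance metrics: accuracy with Wilson score intervals,
    information transfer rate in the Wolpaw formulation, bootstrap group
    intervals, signed-r2 separability maps and stimulus-level AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
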
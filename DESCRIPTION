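Package: qeeg
Title: Quantitative EEG Biomarkers for Stroke Treatment Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Resting-state quantitative electroencephalography (EEG) analysis
    for two-group, two-timepoint clinical studies of stroke recovery.
    Implements relative band power via Welch's method, Lempel-Ziv (LZ76)
    complexity and approximate entropy of the affected hemisphere, a
    deterministic preprocessing chain (bandpass, average reference,
    amplitude-thresholded epoch selection), the associated statistical
    battery (paired and independent t-tests, chi-square, Pearson
    correlation with NIHSS change, Benjamini-Hochberg FDR), EDF input and
    output, and a calibrated synthetic-cohort generator so that every stage
    is testable without patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'RcppExports.R'
    'qeeg-package.R'
    'classes.R'
    'edf.R'
    'features.R'
    'io.R'
    'nonlinear.R'
    'pipeline.R'
    'preprocess.R'
    'spectral.R'
    'stats.R'
    'synthetic.R'
    'transfer.R'
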
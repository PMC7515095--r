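Package: eegmia
Title: Multiscale Information Analysis of High-Frequency EEG Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Feature extraction and evaluation pipeline for four-quadrant
    valence-arousal emotion recognition from multichannel EEG. Implements
    multiscale sample entropy and the multiscale EEG complexity index (MECI)
    in the time domain, ensemble empirical mode decomposition (EEMD) with
    per-IMF energy and sample/fuzzy/Renyi entropy in the frequency domain,
    classical comparison features (box-counting fractal dimension, windowed
    sample entropy, db4 wavelet band energies), per-subject cross-validated
    RBF-SVM classification with confusion-matrix metrics and averaged ROC,
    channel/region significance analysis, and a seeded generator of labelled
    synthetic EEG recordings so the whole pipeline runs without external
    data. EDF/BDF readers and a plain-matrix fallback are included.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    e1071,
    nortest,
    car,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
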
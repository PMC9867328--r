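Package: fractalEEG
Title: Comparative EEG Feature Sets for Valence-Arousal Emotion Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing EEG feature families for binary emotion
    classification on the valence-arousal circumplex. Implements a standard
    signal-conditioning chain (notch, 1 Hz high-pass, down-sampling to 128 Hz,
    common average reference, 2 s epoching, +/-100 uV artifact rejection), five
    per-channel per-epoch feature sets (time-domain statistics, Morlet
    continuous-wavelet summaries, Katz/Petrosian/Higuchi fractal dimensions,
    Hjorth mobility and complexity, and bispectral higher-order spectra),
    subject-dependent nested cross-validation with an RBF-kernel SVM and a
    random-undersampling boosted CART ensemble, and paired feature-set
    comparison statistics (paired t-tests with Holm-Bonferroni correction and
    Cliff's delta). A synthetic-EEG generator with planted fractality
    (Hurst exponent), alpha-band power, and quadratic-phase-coupling class
    differences makes the whole pipeline testable without access to
    license-gated emotion EEG corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    signal,
    e1071,
    rpart,
    jsonlite,
    data.table,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
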
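Package: voicedysph
Title: Multicepstral Multiprojection Detection of Dysphonia in Sustained Vowels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects dysphonic voice from sustained-vowel recordings.
    Implements eight cepstral-coefficient extractors (MFCC, inverse MFCC,
    linear-, bark-, gammatone- and normalized-gammachirp-frequency cepstral
    coefficients, LPCC and constant-Q cepstral coefficients) with delta
    dynamics and cepstral mean-variance normalization; a multiprojection
    operator that compresses each coefficient-by-frame matrix to a compact
    vector through sum, standard-deviation, skewness and principal-component
    mappings; a battery of noncepstral acoustic measures (fundamental
    frequency statistics, jitter, shimmer, harmonic-to-noise ratio, formant
    statistics and vocal-tract length estimates); and a detection pipeline
    with SMOTE class balancing, truncated-SVD reduction, feature
    normalization and SVM, random-forest or logistic-regression classifiers.
    A source-filter synthesizer of sustained vowels with controllable
    fundamental frequency, jitter, shimmer, harmonic-to-noise ratio and
    formants generates labelled two-class corpora for development and
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    e1071,
    randomForest,
    glmnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
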
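Package: mieeg
Title: Motor-Imagery EEG Feature Extraction, Significance Screening and
    Cross-Validated Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for motor-imagery electroencephalography
    (EEG) brain-computer interface experiments. Extracts 1,364 features per
    22-channel, 3-second EEG segment from four families (24 time-domain
    descriptors, FFT subband energy/variance/entropy, Haar wavelet-packet
    subband energy/variance/entropy over the five canonical EEG bands, and
    lagged Poincare plot descriptors SD1/SD2 at lags 1 and 9), screens
    features by statistical significance (independent t-test for two
    classes, one-way ANOVA for more), and evaluates classifiers with
    repeated stratified k-fold cross-validation, including a random-subspace
    regularized-discriminant ensemble. A class-conditioned synthetic EEG
    generator with event-related-desynchronization-like band-power effects
    provides ground-truth data for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    MASS,
    rpart,
    e1071
Suggests:
    testthat (>= 3.0.0),
    class,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
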
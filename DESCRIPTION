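Package: breathomics
Title: Non-Volatile Breathomics Analysis for Direct-Infusion FT-ICR Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of non-volatile organic compounds measured in
    exhaled breath by direct-infusion Fourier-transform ion-cyclotron-resonance
    mass spectrometry. Covers exact-mass molecular formula annotation with
    isotopic fine-structure scoring, local-list m/z recalibration, probabilistic
    quotient and QC-anchored normalization, dual-polarity and dual-method
    feature merging, replicate consensus and prevalence filtering, and a
    three-method significance consensus (volcano with FDR, PLS-DA with VIP
    scores, random forest with out-of-bag error) plus chemical-class coverage
    of the detected metabolome. Includes a synthetic cohort generator with
    known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
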
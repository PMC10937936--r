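Package: vowelpap
Title: Vowel Acoustics and Upper-Airway Diameter Analysis for Sleep Apnea Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to study upper-airway narrowing through sustained vowel
    acoustics. Generates synthetic cohorts of controls and individuals at high
    risk of obstructive sleep apnea (NoSAS score), with parasagittal
    anterior-posterior (PAP) airway diameters and source-filter vowel
    waveforms; extracts a 106-scalar acoustic feature set (pitch, LPC
    formants, Welch band power, spectral centroid, MFCC, chroma, contrast,
    roll-off, zero-crossing rate, spectral shape); runs the group-comparison
    statistics (normality-gated t/rank tests, one-way and mixed repeated
    measures ANOVA, feature-PAP correlations); and estimates PAP diameter
    from acoustic features with a six-fold cross-validated two-step stacked
    regression (linear, random forest, neural and convolutional models
    combined by a random forest).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    randomForest,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
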
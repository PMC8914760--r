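Package: ppgbp
Title: Cuffless Blood Pressure Estimation from PPG Morphology with
    Exponential-Kernel Gaussian Process Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates systolic and diastolic blood pressure from
    single-channel photoplethysmography (PPG) waveforms.  Provides a
    synthetic cohort generator with known ground truth, zero-phase
    band-pass preprocessing and pulse delineation, extraction of eight
    PPG morphology parameters averaged over 15-second windows,
    exponential-kernel Gaussian process regression fitted by marginal
    likelihood maximization, gender-by-age-group model banks with
    feedback calibration against a reference cuff reading, and the
    device-validation statistics used in the field (AAMI bound, BHS
    grading, Bland-Altman limits of agreement, Pearson correlation,
    Shapiro-Wilk normality, interval-mode subgroup breakdown and an
    age-grouping-width sweep).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
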
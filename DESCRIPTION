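Package: spindlespa
Title: Interhemispheric Sleep Spindle Power Asymmetry Analysis for Infant EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated analysis of interhemispheric sleep spindle power
    asymmetry (SPA) in infant N2-sleep EEG after unilateral perinatal brain
    injury. Reads EDF recordings, applies zero-phase band-pass filtering and a
    standard bipolar montage, detects sleep spindles (11-15 Hz) per derivation
    with a sigma-envelope threshold detector, aggregates event powers into 15
    regional/band SPA indexes (lesioned over non-lesioned hemisphere), and
    evaluates SPA as an outcome biomarker: Mann-Whitney group comparisons,
    forward-conditional logistic selection, ROC/AUC, fixed-cutoff diagnostics
    and Grubbs outlier screening. Includes a seeded synthetic-EEG cohort
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
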
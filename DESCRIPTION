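Package: seatsway
Title: Seated Posturography: CoP Trajectories, Spectral Band Power and
    Group Classification from Balance-Board Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for seated postural-control recordings made
    on a four-load-cell balance board. Converts raw corner-force signals
    into filtered center-of-pressure (CoP) trajectories, extracts sway
    features (track length, power spectral density band areas, per-cycle
    peak acceleration, ellipticity), applies staged quality-control
    filters, computes two-group comparisons and factorial ANOVA with
    effect sizes and post-hoc power, and benchmarks four classifiers
    (SVM, decision tree, random forest, neural network) on repeated
    train/test splits. Includes a seeded synthetic-cohort generator that
    emulates healthy and low-back-pain sway so the whole pipeline is
    testable without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    car,
    e1071,
    rpart,
    randomForest,
    nnet
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
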
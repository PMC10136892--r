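Package: petrad
Title: Whole-Body PET-CT Radiomics for Immunotherapy Response and
    Progression-Free Survival Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible radiomics pipeline for baseline FDG-PET-CT of
    advanced non-small-cell lung cancer under checkpoint-inhibitor therapy.
    Segments FDG-positive tumour burden with a PERCIST-style liver-referenced
    SUV threshold, extracts an 84-feature signature (first-order, shape and
    grey-level co-occurrence texture) per modality and reader, filters
    features by inter-reader concordance (Lin's CCC), selects predictive
    features with a Boruta shadow-feature random forest followed by
    correlation pruning, models response with logistic regression and
    ROC/Youden cutpoints, and analyses progression-free survival with
    Kaplan-Meier, log-rank and Cox proportional-hazards fits. Because the
    underlying patient images are not public, the package ships a synthetic
    phantom-cohort generator that emulates the statistical structure the
    analysis assumes, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    ranger,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
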
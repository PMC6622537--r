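Package: oncoforest
Title: Random-Forest Prediction of Anticancer Drug Sensitivity from
    Minimal Oncogene Mutation Profiles and Chemical Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and validates random-forest models that predict the
    activity (IC50-thresholded classification) and log10(IC50) (regression)
    of anticancer compounds against cancer cell lines, using binary oncogene
    mutation profiles joined with 1216-element chemical descriptor
    fingerprints.  Implements entropy-based oncogene panel selection, Gini
    importance ranking and minimal-gene-set search, SMOTE class balancing,
    activity-cutoff ROC sweeps, y-randomization controls, leave-drug-out
    blind validation, missing-activity imputation benchmarks, and dummy
    baselines, together with a synthetic screening-data generator with
    planted gene-by-chemistry interaction effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    glmnet,
    rpart,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR,
    ChemmineOB,
    class
Config/testthat/edition: 3
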
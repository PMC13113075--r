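Package: vocpartition
Title: Hierarchical Variance Partitioning and Subject-Wise Validation for Pig Vocal Distress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing distress encoding in pig vocalizations from
    tabular acoustic features. Partitions trait variance into distress,
    growth-phase, sex and individual (animal) components with linear
    mixed models (intraclass correlations, marginal and conditional R2,
    drop-one delta-R2, interaction selection, Benjamini-Hochberg FDR);
    benchmarks multi-class distress classification under animal-grouped
    cross-validation with leakage-free within-fold imputation and scaling;
    summarises class confusability (directional and symmetric confusion,
    prediction entropy and margin, phase-stratified overlap, cluster
    stability) and grouped-fold permutation importance. Includes a
    synthetic-data generator reproducing the nested experimental design
    (animal, growth phase, distress condition, recording, sample) with
    structured missing-not-at-random pitch.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    nnet,
    ranger,
    xgboost,
    mclust,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
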
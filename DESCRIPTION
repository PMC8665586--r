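Package: abatn
Title: Predicting Tau Pathology and Neurodegeneration Status from CSF
    Amyloid-Beta Isoforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying whether cerebrospinal-fluid amyloid-beta
    isoforms (Abeta1-38, Abeta1-40, Abeta1-42) predict tau-pathology
    positivity (T+) and neurodegeneration positivity (N+) in cognitively
    unimpaired individuals.  Provides a calibrated synthetic-cohort
    generator (moment-matched multivariate lognormal isoform model with
    threshold-consistent tau labels), exhaustive feature-subset model
    selection by nested cross-validation over nine classifier families,
    rank-based and binormal AUC statistics, group comparisons
    (Mann-Whitney, Welch t, Fisher exact), an empirical-Bayes moderated-t
    differential-expression analysis for peptide panels with a
    detectability filter and Benjamini-Hochberg FDR control, and
    hypergeometric over-representation analysis of GMT gene sets with
    Jaccard term networks, including contrasts stratified by classifier
    prediction outcome (TP/FP/TN/FN).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    glmnet,
    e1071,
    ranger,
    rpart,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
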
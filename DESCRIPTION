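Package: mepmuscle
Title: Muscle Classification of Intraoperative Motor Evoked Potentials
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying intraoperative motor evoked potential (MEP)
    recordings according to the muscle they were recorded from. Provides a
    calibrated synthetic MEP cohort generator (four muscles, patient-wise
    amplitude scaling, stimulation-artifact trains, class imbalance via blank
    traces), EDF-based cohort import/export, peak-prominence based MEP
    preselection and per-patient normalization, exploratory feature extraction
    (onset/peak/end latencies, extrema, area under the curve, peak counts),
    PCA compression, patient-disjoint train/test splitting with SMOTE class
    balancing, grid-search tuning and training of random forest, k-nearest
    neighbor and logistic regression classifiers over three muscle-comparison
    paradigms and three data representations, and the associated evaluation
    metrics (accuracy, macro F1, one-vs-rest ROC AUC, confusion matrices with
    limb-level aggregation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    caret,
    ranger,
    glmnet,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, Preprocessing, TimeCourse, Electrophysiology
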
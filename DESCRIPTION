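Package: vocpanel
Title: Urinary Volatile-Compound Biomarker Discovery by SVM Panel Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for discovering diagnostic panels of
    urinary volatile organic compounds (VOCs) from GC/MS peak tables in
    case/control rodent tumor studies. Covers simulation of four-group,
    two-timepoint peak-height studies and raw total-ion chromatograms;
    chromatogram peak-window detection and quantification; log transformation
    and per-sample intensity normalization; removal of the shared
    early-to-terminal "term effect" by per-animal subtraction; univariate
    screening; balanced two-way ANOVA interaction screening for tumor-model
    specificity; PCA projection and soft-margin RBF support-vector
    classification; and exhaustive peak-subset panel search evaluated by
    k-fold cross-validation, hold-out splits and cross-model transfer, with
    sensitivity/specificity/accuracy reporting in ROC space.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'anova.R'
    'chromatogram.R'
    'features.R'
    'io.R'
    'metrics.R'
    'panel.R'
    'pca.R'
    'pipeline.R'
    'plots.R'
    'svm.R'
    'synthesize.R'
    'utils.R'
    'vocpanel-package.R'
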
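Package: HistoDensity
Title: Histologic Correlates of Mammographic Density from Tissue-Class Maps
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies breast tissue architecture from whole-slide
    tissue-class label maps (epithelium, stroma, fat) and relates it to
    mammographic breast density and biopsy diagnosis. Computes a 37-feature
    vector per slide covering global tissue quantities, epithelial-region
    morphology, area-Voronoi influence zones and Delaunay neighbor graphs;
    fits random-forest models predicting percent fibroglandular volume with
    impurity-based importance ranking and correlated-feature pruning; trains
    invasive-vs-benign classifiers within high/low density strata; and
    evaluates them with ROC/AUC, class-stratified percentile-bootstrap
    confidence intervals and bootstrap AUC comparisons. Includes a synthetic
    label-map cohort generator with controllable composition and epithelial
    spatial organization for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    randomForest,
    png,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
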
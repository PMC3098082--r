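Package: gsbench
Title: Gene-Selection Workbench with .632+ Bootstrap Model Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatically builds, evaluates and ranks gene-selection
    procedures for two-class gene-expression matrices. Procedures combine a
    feature-ranking statistic (Welch t-test, Wilcoxon rank-sum, or
    information gain with MDL entropy discretization), optional restriction
    to up- or down-regulated genes, top-k selection, optional feature
    discretization and feature-vector addition, and an SVM or random-forest
    classifier. Each procedure is scored by the .632+ bootstrap error with
    feature selection re-run inside every resample, and the grid report
    ranks procedures by error and parsimony. Includes a synthetic two-class
    expression-data generator with planted differential genes, a
    tab-delimited reader/writer, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    randomForest,
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
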
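Package: geolabel
Title: Two-Stage Age, Sex and Tissue Labeling of GEO Expression Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Assigns age, sex and tissue labels to Gene Expression Omnibus
    (GEO) samples in two stages. Stage one extracts labels from free-text
    sample metadata using regular-expression heuristics with unit
    normalization and dictionary matching of tissue-ontology term names and
    synonyms (Aho-Corasick multiple string search with shallowest-node
    selection). Stage two trains one-vs-rest logistic-regression classifiers
    on gene expression vectors, using the text-derived labels, to fill in
    samples whose metadata lacks a label. Includes the supporting
    normalization chain (probe collapse, quantile normalization, KNN
    imputation), ANOVA-F feature selection, experiment-stratified
    cross-validation, precision-recall and ontology-distance evaluation, and
    synthetic generators for metadata corpora, toy ontologies and labeled
    expression matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    limma,
    glmnet,
    pROC,
    DBI,
    RSQLite,
    Matrix,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
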
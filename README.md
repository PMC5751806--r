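# geolabel

Two-stage assignment of **age, sex and tissue labels** to Gene Expression
Omnibus (GEO) expression samples.

Most GEO samples describe their donor's age, sex and tissue only in free
text — the title, description, source name and the semi-structured
"Characteristics" key–value block — which makes large-scale reuse of the
data (meta-analysis, reference atlases, classifier training) needlessly
hard. geolabel recovers those attributes as machine-readable labels:

1. **Text stage (precision-first).** Regular-expression heuristics extract
   sex (`gender: male`, `sex: M`, `sex: 1`) and age (`age: 29 y`,
   `age (mo): 520`, bare `age: 47` with species default units), convert
   ages to years (1 y = 12 mo = 365.25 d) and discard values outside a
   plausible range. Tissues are found by Aho–Corasick dictionary matching
   of OBO ontology term names and synonyms; among multiple matches the
   *shallowest* (most general) term wins. Fields are searched in the order
   Characteristics → Description → Source Name → Title → everything else,
   stopping at the first field that yields a label.
2. **Expression stage (recall fallback).** For samples the text leaves
   unlabeled, a one-vs-rest L2-regularized logistic regression over the
   sample's gene expression vector — preprocessed by probe collapse
   (highest-mean probe per gene), quantile normalization and KNN(5)
   imputation, reduced to the 100 genes with the largest one-way ANOVA F
   statistic — predicts sex or tissue. Text labels always take precedence;
   ML predictions are accepted only above a probability threshold. Age is
   not predicted from expression.

Evaluation is **experiment-stratified**: in cross-validation all samples
of a series share a fold, because samples within an experiment resemble
each other far beyond their labels and naive CV rewards recognizing the
experiment. The package reports micro/macro precision–recall, confusion
matrices, age MAD/MSE with a within-one-month rule, ontology-distance
error profiles against a random-pair baseline, and a dummy-classifier
floor.

Synthetic generators (`genMetadata()`, `genToyOntology()`,
`genExpression()`) emulate metadata corpora with the label-presence rates
observed in GEO (sex 26%, age 21%, tissue 86%), toy ontology DAGs, and
expression matrices with planted label-informative genes and per-series
random intercepts — so the whole pipeline builds and tests without any
download.

## Worked example

```r
library(geolabel)

m <- sampleMetadata("GSM17122", organism = "Mus musculus",
  characteristics = c(`1` = paste(
    "Genetic Background: NOD; Transgene: BDC2.5 T cell receptor genes;",
    "Age: 25 days; Tissue: Pancreas;",
    "Isolation: FACS on CD45+ Hoechst- (viable) cells")))

age <- extractAge(m)
## age: 25 days (0.0684 years, field characteristics_ch1)

g <- loadOBO(system.file("extdata", "toy_tissues_synthetic.obo",
                         package = "geolabel"))
tissue <- matchTissue(m, fieldOrder(), buildMatcher(g), g)
## tissue: pancreas (TOY:0000004, depth 3, matched "Pancreas")
```

The age extractor found the `Age` pair, read the unit from the value text
and converted 25 days to 0.0684 years; the matcher found the `Tissue` pair
and mapped its value to the ontology term at depth 3. On a synthetic
corpus with planted labels, the closed loop looks like this:

```r
g2 <- genToyOntology(nTerms = 40, seed = 2)
corpus <- genMetadata(corpusSpec(nSamples = 500, nSeries = 25, seed = 2), g2)
extractAll(corpus$metadata, graph = g2)$coverage
##   sex    age tissue
## 0.230  0.178  0.824

se <- genExpression(expressionSpec(seed = 2), corpus$truth)
y <- setNames(corpus$truth$sex, corpus$truth$sample_id)
cv <- crossValidate(se, y, "sex", mlConfig(seed = 2),
                    folds = makeFolds(corpus$truth$series_id, 10, 2))
## sex CV macro P/R: 0.954 / 0.949 ; macro AUC 0.992 ; dummy AUC 0.520
```

Text coverage sits near the planted presence rates (every emitted label is
correct — the adversarial template families do not fire), and the
expression classifier recovers the planted sex signal under
experiment-stratified 10-fold CV while the expression-blind dummy baseline
stays at chance.

A command-line wrapper ships at
`system.file("scripts", "ale", package = "geolabel")` with subcommands
`extract`, `train`, `predict`, `evaluate`, `synth` and `onto-dist`; see
`aleMain()` for the options.

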
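---
title: "Labeling GEO samples from metadata text and expression: methods"
author: "geolabel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Labeling GEO samples from metadata text and expression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geolabel)
```

## The problem

Public repositories such as the Gene Expression Omnibus (GEO) hold enormous
numbers of expression samples whose basic attributes — donor age, sex,
tissue of origin — live only in free-text fields the submitter chose to
write (title, description, source name, and the semi-structured
"Characteristics" key–value block). Large-scale reuse of these data
(meta-analysis, reference building, model training) needs those attributes
as machine-readable labels.

geolabel produces them in two stages:

1. **Text stage.** Precision-first heuristics over the metadata: regular
   expressions for sex and age (with unit detection, species default units,
   conversion to years and plausibility bounding), and dictionary matching
   of tissue-ontology term names and synonyms using the Aho–Corasick
   multiple-string-search algorithm, selecting the *shallowest* (most
   general) matched term.
2. **Expression stage.** For samples the text does not label, a one-vs-rest
   (OVR) L2-regularized logistic regression over the sample's own gene
   expression vector, trained on the text-derived labels, predicts sex or
   tissue. Age is deliberately *not* predicted from expression.

A text label, when present, always wins over a machine-learning prediction
(`combineLabels()`): the heuristics are engineered for precision at the
expense of recall, and the classifier exists to recover recall on the
remainder.

## Text-stage model and assumptions

**Field search order.** All extractors search `characteristics`,
`description`, `source_name`, `title`, then any extra fields, and *stop at
the first field class that yields a label*. The Characteristics block is
trusted most because its keys are attributes the experimenter explicitly
named. Within it, pairs whose key names the attribute (`sex`/`gender`,
`age`, `tissue`/`organ`/`cell type`/`source`) are inspected before the
remaining pairs. Channel 1 is searched before channel 2; one-color arrays
dominate GEO, so multi-channel records are rare.

**Characteristics parsing.** A raw cell is split into pairs on `;`, tab or
newline (configurable — the flat-file encoding of the pairs is not
standardized), and each pair on its *first* colon, so values may contain
colons. The parse is total: malformed segments become a pair with an empty
key.

**Sex.** Value vocabulary `male`/`m`/`man` and `female`/`f`/`woman`,
matched case-insensitively on whole tokens; the numeric coding `1` = male,
`0` = female is accepted only under an explicit sex/gender key and carries
confidence 0.5 (all lexical matches carry 1.0). In free text only explicit
`sex: M`-style patterns fire; a bare "male" in a title does not, because
phrases like "male-derived reference pool" would poison precision.
Contradictory matches within one field class yield no label and a warning.
Implicit forms such as `"patient X (34, F, non-smoker)"` are matched only
under the opt-in `aggressive` flag. The vocabulary ships as a plain-text
TSV (`defaultPatternTable()`) so curators can extend it without code
changes, and every fired pattern is recorded in the label's `matchedText`
for audit.

**Age.** Three recognized shapes: `age: 29 y` (unit in the value),
`age (mo): 520` (unit in the key), and bare `age: 47`. Unit tokens are
resolved through a synonym table (`y/yr/yrs/year/years`, `mo/mos/mon/...`,
`w/wk/wks/...`, `d/day/days`). When no unit is recognized the *species
default* applies — years for human, months for rodents (decided by
`mus`/`rattus` substrings of the organism field) — and the label is
flagged `unitWasDefault`. An unrecognized token (typically a misspelled
unit) is treated as absent, which reproduces the characteristic failure
mode of this design: a rodent age in misspelled months silently becomes
years. That is why extracted ages are bounded: canonical values outside
`[0, 120]` years (configurable; 0 kept inclusive so neonates survive, with
the flag available for scrutiny) are discarded with a warning. Conversion
constants: 1 year = 12 months = 365.25 days, 1 week = 7 days.

**Tissue.** All non-obsolete term names and synonyms of an OBO ontology
(every synonym scope is indexed; the scope is recorded) become patterns of
an Aho–Corasick automaton, so one pass over a text finds every occurrence
of every pattern. Two knobs guard against the ontology's short generic
synonyms ("bud", "cap"): matches must be token-bounded (non-alphanumeric
or text edge on both sides; raw substring matching is available by
configuration) and patterns shorter than 3 characters are not indexed; an
explicit stoplist is also available (empty by default). Among the hits of
the first field group that yields any, the term with *minimal depth* —
shortest `is_a` path to a root, under multiple parentage the shortest route
— is selected: a more general term is more likely to be correct, at the
price of informativeness. Ties break deterministically (longer matched
surface string, then smallest term id). Matching is exact: "ovarian" does
not map to "ovary"; fuzzy matching is out of scope.

## Expression-stage model

The classifier consumes a gene-level, log-scale matrix produced by a fixed
chain: log2(x+1) if the matrix maximum exceeds 30 (a value no log-scale
microarray matrix reaches; overridable), probe collapse keeping, per gene,
the probe with the highest mean expression across samples (mean ties to
the lexicographically smallest probe id), between-array quantile
normalization (via limma, tie values averaged), and k-nearest-neighbor
imputation with k = 5. Imputation neighbors are *samples*, ranked by
Euclidean distance over mutually observed genes scaled to per-gene units
so unequal overlap does not bias the ranking; neighbors that observe the
missing gene contribute their mean, and a gene observed nowhere near falls
back to its global mean. On clean gene-level data the whole chain is
idempotent to 1e-9.

Feature selection is two-stage: drop genes with variance at or below a
threshold (default 0, i.e. only constant genes), then rank the rest by the
one-way ANOVA F statistic of expression against the class label and keep
the top `nFeatures` (default 100; ties to the smaller gene id). One
binary ridge logistic regression per class (glmnet, `alpha = 0`,
`lambda = 1/(nC)` with `C = 1` by default, no standardization) is fitted
on the selected submatrix; prediction normalizes the per-class sigmoid
scores to sum to one and reports the argmax. Tissue is treated as
single-label multiclass: an ontology's general nodes (e.g. "blood")
subsume their specific descendants, which is what makes the single-label
reduction defensible. Age is rejected as a prediction target — it is a
continuous quantity whose expression signal is weak and whose text signal
is precise, and the API enforces that boundary with a clear error.

**No leakage.** Feature selection runs inside each training fold, never on
held-out data.

## Evaluation machinery

Cross-validation is *experiment-stratified*: series are packed greedily
(largest first, seeded tie shuffle) into the currently smallest of k = 10
folds, so all samples of a series share a fold. Samples within an
experiment resemble each other far beyond their labels, and naive CV lets
a classifier score by recognizing the experiment; `makeNaiveFolds()` is
provided purely to demonstrate that inflation.

Precision/recall come in per-class, micro (pooled) and macro (unweighted
class mean) forms. Abstentions count as false negatives for recall but
never enter a precision denominator — the right accounting for a
precision-first extractor. A class that is never predicted has undefined
precision; it is reported as NaN per class, contributes 0 to the macro
mean, and the count of such classes is attached. Evaluations can be
restricted to the top-M most frequent classes with a support floor
(defaults M = 25, floor 10 in headline-style summaries). Age error is
reported as MAD (years), MSE (years²) and the fraction of predictions
within one month (|error| ≤ 1/12 year). Tissue error is profiled as the
distribution of undirected shortest-path distances between predicted and
true terms, next to a baseline of uniformly sampled term pairs; per-class
one-vs-rest AUCs are averaged unweighted into a macro AUC, with a seeded
dummy classifier (draws from the training label distribution, one-hot
scores) as the floor.

## What the synthetic generators emulate

`genMetadata()` plants known sex/age/tissue into generated records at the
rates observed in real GEO metadata (sex 26%, age 21%, tissue 86%), with
ages from a truncated Normal(46.7, 21.6²) on [0, 95] years, phrased
through weighted template families: explicit key-value, abbreviated,
numeric-coded, unit-in-key, bare number, misspelled unit, implicit
parenthetical, and a derived-adjective tissue form. The last two families
(and the out-of-range part of the misspelled-unit family) are adversarial:
the extractors must *not* fire on them, which the truth table's
`*_expected` flags make exactly testable — reported coverage must equal
the flags' mean, and any extra firing is a precision failure. Label
structure follows real experiments: half the series are single-sex cohorts
and each series has a dominant tissue carried by 80% of its samples.
Without that within-series label structure the leakage that
experiment-stratification guards against would barely exist in the
fixture.

`genExpression()` draws log-scale Gaussian intensities: per-gene baselines
around 7, per-series per-gene random intercepts (sd 0.5 by default) that
correlate samples of an experiment, a class shift of `effectSize` (default
1.0 log2 units — conservative next to real sex-chromosome genes) on 20
informative genes per label, noise sd 1.0, optional missing entries.
`genToyOntology()` grows a rooted DAG with diamonds and synonyms and
recomputes its own depths incrementally as an independent check.

What passing these tests does **not** show: robustness to real GEO's
spelling variation, multi-tissue samples, platform effects beyond a series
intercept, count-based RNA-seq distributions, or ontologies at BTO scale
(thousands of terms); the automaton is algorithmically linear in text
length but its R implementation is tuned for fixture-scale dictionaries.

## Numerical choices and problem sizes

All randomness flows through per-call integer seeds; generators are
bit-reproducible. The shipped analyses use desk-scale sizes chosen to
exercise every code path while keeping the full suite fast: corpora of
80–1000 samples over 6–40 series, ontologies of 17–40 terms, and a
recovery experiment of 2000 genes × 500 samples over 25 series under
10-fold stratified CV — the regime in which the sex classifier reaches
macro precision/recall above 0.9 while the dummy baseline's AUC stays
near 0.5. Degenerate inputs are defined, not crashed: empty
characteristics parse to empty tables, single-sample matrices skip
quantile normalization with a warning, a single-term ontology yields
all-zero distances, unreachable term pairs report infinite distance, and
fewer surviving genes than requested features returns them all with a
warning.

## Known limitations

- Exact string matching only; no fuzzy matching or synonym expansion
  beyond the ontology's own synonyms.
- The 0/1 sex coding polarity (1 = male) is a convention, flagged at
  confidence 0.5 rather than assumed reliable.
- Quantile normalization is computed jointly over the samples of one
  input matrix; cross-platform batch correction is out of scope.
- The dummy baseline and AUC averaging use one specific convention
  (stratified draws; unweighted one-vs-rest mean); other conventions give
  slightly different numbers.
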
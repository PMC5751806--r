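#' @import methods
NULL

#' SampleMetadata: one GEO sample's textual metadata
#'
#' Holds the free-text fields of a single GEO sample record as stored in a
#' GEOmetadb-style table: accessions, organism/molecule, title, description,
#' and the per-channel source-name and characteristics fields. The raw
#' characteristics string of each channel is parsed eagerly into an ordered
#' key-value table (see [parseCharacteristics()]); the parsed form is kept in
#' sync with the raw form, which the validity method checks.
#'
#' @slot sampleId GEO sample accession (e.g. `"GSM17122"`); must be nonempty.
#' @slot seriesId GEO series (experiment) accession, possibly `""`.
#' @slot platformId GEO platform accession, possibly `""`.
#' @slot organism species string, e.g. `"Homo sapiens"`.
#' @slot molecule assay molecule string (`"total RNA"` etc.).
#' @slot title,description free text, possibly `""`.
#' @slot sourceName named character vector of per-channel source-name text;
#'   names are channel numbers (`"1"`, `"2"`, ...).
#' @slot characteristicsRaw named character vector of per-channel raw
#'   characteristics text; names are channel numbers.
#' @slot characteristics named list (one element per channel) of data frames
#'   with columns `key`, `value`, in order of appearance in the raw text.
#' @slot extraFields named character vector of any other metadata columns.
#'
#' @seealso [sampleMetadata()] for the user constructor.
#' @export
setClass("SampleMetadata",
  representation(
    sampleId = "character",
    seriesId = "character",
    platformId = "character",
    organism = "character",
    molecule = "character",
    title = "character",
    description = "character",
    sourceName = "character",
    characteristicsRaw = "character",
    characteristics = "list",
    extraFields = "character"
  ),
  prototype(
    seriesId = "", platformId = "", organism = "", molecule = "",
    title = "", description = "", sourceName = character(),
    characteristicsRaw = character(), characteristics = list(),
    extraFields = character()
  )
)

setValidity("SampleMetadata", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || is.na(object@sampleId) ||
      !nzchar(object@sampleId))
    msg <- c(msg, "sampleId must be a single nonempty string")
  chn <- names(object@characteristicsRaw)
  if (length(chn) && any(is.na(suppressWarnings(as.integer(chn))) |
                         suppressWarnings(as.integer(chn)) < 1L))
    msg <- c(msg, "characteristics channel numbers must be positive integers")
  if (!identical(names(object@characteristics),
                 names(object@characteristicsRaw)))
    msg <- c(msg, "characteristics channels must mirror characteristicsRaw")
  for (ch in names(object@characteristicsRaw)) {
    reparsed <- parseCharacteristics(object@characteristicsRaw[[ch]])
    if (!identical(reparsed, object@characteristics[[ch]]))
      msg <- c(msg, sprintf(
        "characteristics channel %s is not the parse of characteristicsRaw", ch))
  }
  if (length(msg)) msg else TRUE
})

#' OntologyGraph: a tissue ontology as a DAG of terms
#'
#' In-memory representation of an OBO ontology: every term has a primary
#' name, zero or more synonyms (with their OBO scope), and `is_a` parent
#' links. The term graph must be acyclic; depths (shortest directed path up
#' to a root) are precomputed at construction time.
#'
#' @slot termIds character vector of term identifiers.
#' @slot termNames character vector of primary names, parallel to `termIds`.
#' @slot synonyms list (parallel to `termIds`) of data frames with columns
#'   `text`, `scope`.
#' @slot parents list (parallel to `termIds`) of character vectors of parent
#'   term ids (`is_a` targets).
#' @slot obsolete logical vector; obsolete terms are kept in the graph but
#'   excluded from dictionary matching.
#' @slot depths integer vector of shortest-path depths (root = 0).
#' @slot graph an [igraph::igraph] directed graph (edges child -> parent).
#'
#' @seealso [loadOBO()], [termDepth()], [ontologyDistance()]
#' @export
setClass("OntologyGraph",
  representation(
    termIds = "character",
    termNames = "character",
    synonyms = "list",
    parents = "list",
    obsolete = "logical",
    depths = "integer",
    graph = "ANY"
  )
)

setValidity("OntologyGraph", function(object) {
  msg <- character()
  n <- length(object@termIds)
  if (anyDuplicated(object@termIds))
    msg <- c(msg, "term ids must be unique")
  if (length(object@termNames) != n || length(object@synonyms) != n ||
      length(object@parents) != n || length(object@obsolete) != n ||
      length(object@depths) != n)
    msg <- c(msg, "parallel slots must all have one entry per term")
  unknown <- setdiff(unique(unlist(object@parents)), object@termIds)
  if (length(unknown))
    msg <- c(msg, paste0("parent ids not in ontology: ",
                         paste(unknown, collapse = ", ")))
  if (n > 0 && !igraph::is_dag(object@graph))
    msg <- c(msg, "is_a graph must be acyclic")
  if (length(msg)) msg else TRUE
})

#' Extracted sample labels
#'
#' `SampleLabel` is the virtual parent of the three label classes produced by
#' the text extractors and the expression classifiers. All labels carry
#' provenance: which metadata field matched, the exact surface text, whether
#' the label came from text heuristics or from the ML fallback, and a
#' confidence in `[0, 1]`.
#'
#' @slot sampleId sample accession the label belongs to (may be `""` when the
#'   label is constructed outside a corpus context).
#' @slot source `"text"` or `"ml"`.
#' @slot matchedField name of the metadata field that matched (e.g.
#'   `"characteristics_ch1"`), `""` for ML labels.
#' @slot matchedText the exact surface string that fired, `""` for ML labels.
#' @slot confidence number in `[0, 1]`.
#' @aliases SexLabel-class AgeLabel-class TissueLabel-class
#' @export
setClass("SampleLabel",
  representation("VIRTUAL",
    sampleId = "character",
    source = "character",
    matchedField = "character",
    matchedText = "character",
    confidence = "numeric"
  ),
  prototype(sampleId = "", source = "text", matchedField = "",
            matchedText = "", confidence = 1)
)

setValidity("SampleLabel", function(object) {
  msg <- character()
  if (!object@source %in% c("text", "ml"))
    msg <- c(msg, "source must be 'text' or 'ml'")
  if (object@confidence < 0 || object@confidence > 1)
    msg <- c(msg, "confidence must lie in [0, 1]")
  if (object@source == "text" && !nzchar(object@matchedText))
    msg <- c(msg, "text-source labels must record matchedText")
  if (length(msg)) msg else TRUE
})

#' @rdname SampleLabel-class
#' @slot value for `SexLabel`: `"male"` or `"female"`.
#' @export
setClass("SexLabel", contains = "SampleLabel",
  representation(value = "character"))

setValidity("SexLabel", function(object) {
  if (!object@value %in% c("male", "female"))
    "value must be 'male' or 'female'" else TRUE
})

#' @rdname SampleLabel-class
#' @slot rawValue numeric age as written in the text.
#' @slot rawUnit `"years"`, `"months"`, `"weeks"`, `"days"` or `"unknown"`
#'   (no unit present in the text).
#' @slot valueYears canonical age in years, `convertAge(rawValue, unit)` with
#'   the unit resolved through the species default when absent.
#' @slot unitWasDefault `TRUE` when the unit was not in the text and the
#'   species default was applied.
#' @export
setClass("AgeLabel", contains = "SampleLabel",
  representation(rawValue = "numeric", rawUnit = "character",
                 valueYears = "numeric", unitWasDefault = "logical"))

setValidity("AgeLabel", function(object) {
  msg <- character()
  if (object@rawValue < 0) msg <- c(msg, "rawValue must be nonnegative")
  if (!object@rawUnit %in% c("years", "months", "weeks", "days", "unknown"))
    msg <- c(msg, "rawUnit must be a recognized unit or 'unknown'")
  if (object@rawUnit == "unknown" && !object@unitWasDefault)
    msg <- c(msg, "unknown rawUnit requires unitWasDefault = TRUE")
  if (length(msg)) msg else TRUE
})

#' @rdname SampleLabel-class
#' @slot termId,termName ontology term the text mapped to.
#' @slot depth the term's depth in the ontology (root = 0); equals
#'   `termDepth(graph, termId)` at construction.
#' @export
setClass("TissueLabel", contains = "SampleLabel",
  representation(termId = "character", termName = "character",
                 depth = "integer"))

#' TrainedModel: a fitted one-vs-rest expression classifier
#'
#' One L2-regularized logistic regression per class over a fixed panel of
#' selected genes. Prediction computes per-class sigmoid scores on the
#' selected-gene submatrix and normalizes them across classes.
#'
#' @slot labelType `"sex"` or `"tissue"`.
#' @slot classes ordered character vector of class labels (>= 2).
#' @slot selectedGenes character vector of the gene panel (default 100).
#' @slot weights numeric matrix, genes x classes.
#' @slot intercepts numeric vector, one per class.
#' @slot trainingInfo list with `nSamples`, `seed`, and the `MLConfig` used.
#' @seealso [trainLabelModel()], [predictLabels()]
#' @export
setClass("TrainedModel",
  representation(
    labelType = "character",
    classes = "character",
    selectedGenes = "character",
    weights = "matrix",
    intercepts = "numeric",
    trainingInfo = "list"
  )
)

setValidity("TrainedModel", function(object) {
  msg <- character()
  if (length(object@classes) < 2)
    msg <- c(msg, "a classifier needs at least 2 classes")
  if (!identical(dim(object@weights),
                 c(length(object@selectedGenes), length(object@classes))))
    msg <- c(msg, "weights must be selectedGenes x classes")
  if (length(object@intercepts) != length(object@classes))
    msg <- c(msg, "one intercept per class required")
  if (length(msg)) msg else TRUE
})
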
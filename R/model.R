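#' Expression classifier configuration
#'
#' @param nFeatures size of the selected gene panel (default 100).
#' @param varianceThreshold genes with variance less than or equal to this
#'   are removed before F-scoring; the default 0 drops only constant genes.
#' @param regularizationStrength inverse L2 penalty `C` of the logistic
#'   fits (ridge penalty `lambda = 1 / (n * C)`); default 1.
#' @param knnK imputation neighbors, default 5.
#' @param minClassSize minimum labeled samples per class for training
#'   (default 10).
#' @param seed integer seed recorded in the model and used for any
#'   stochastic component.
#' @return a list with class `"MLConfig"`.
#' @export
mlConfig <- function(nFeatures = 100L, varianceThreshold = 0,
                     regularizationStrength = 1, knnK = 5L,
                     minClassSize = 10L, seed = 1L) {
  stopifnot(nFeatures >= 1, knnK >= 1)
  structure(list(nFeatures = as.integer(nFeatures),
                 varianceThreshold = varianceThreshold,
                 regularizationStrength = regularizationStrength,
                 knnK = as.integer(knnK),
                 minClassSize = as.integer(minClassSize),
                 seed = as.integer(seed)),
            class = "MLConfig")
}

## Vectorized one-way ANOVA F statistic per matrix row.
## F = (between-group SS / (k-1)) / (within-group SS / (n-k)).
rowFStatistic <- function(v, groups) {
  groups <- as.factor(groups)
  n <- ncol(v); k <- nlevels(groups)
  counts <- as.vector(table(groups))
  groupSum <- t(rowsum(t(v), groups))          # genes x k
  groupMean <- sweep(groupSum, 2, counts, "/")
  grand <- rowMeans(v)
  ssb <- rowSums(sweep((groupMean - grand)^2, 2, counts, "*"))
  sst <- rowSums((v - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Select the most label-informative genes
#'
#' Two-stage filter: genes with variance `<= varianceThreshold` are removed,
#' then the one-way ANOVA F statistic of expression against the class label
#' is computed per gene and the `nFeatures` genes with the largest F are
#' returned (ties to the smaller gene id, so selection is deterministic).
#'
#' @param se expression container (genes x samples, no missing values).
#' @param labels character vector of class labels, one per sample (named by
#'   sample id or aligned to columns).
#' @param cfg an [mlConfig()].
#' @return ordered character vector of selected gene ids.
#' @export
selectFeatures <- function(se, labels, cfg = mlConfig()) {
  v <- exprsValues(se)
  labels <- alignLabels(labels, colnames(v))
  keepSamp <- !is.na(labels)
  v <- v[, keepSamp, drop = FALSE]; labels <- labels[keepSamp]
  if (length(unique(labels)) < 2)
    glStop("feature selection needs >= 2 classes", "geolabel_ml_error")
  vars <- apply(v, 1, stats::var)
  v <- v[vars > cfg$varianceThreshold, , drop = FALSE]
  if (!nrow(v))
    glStop("no genes survive the variance filter", "geolabel_ml_error")
  f <- rowFStatistic(v, labels)
  f[!is.finite(f)] <- Inf    # zero within-group variance = perfect separator
  ord <- order(-f, rownames(v))
  if (nrow(v) < cfg$nFeatures)
    warning("only ", nrow(v), " genes survive filtering; returning all")
  rownames(v)[ord[seq_len(min(cfg$nFeatures, nrow(v)))]]
}

alignLabels <- function(labels, sampleIds) {
  if (!is.null(names(labels))) {
    out <- labels[match(sampleIds, names(labels))]
  } else {
    stopifnot(length(labels) == length(sampleIds))
    out <- labels
  }
  out <- as.character(out)
  out[!is.na(out) & out == ""] <- NA
  out
}

#' Train a one-vs-rest logistic-regression label classifier
#'
#' Selects the gene panel with [selectFeatures()] on the training samples
#' only, then fits one L2-regularized (ridge) binary logistic regression
#' per class on the selected-gene submatrix. Age is a continuous label and
#' is not predicted from expression; requesting it is an error.
#'
#' @param se expression container (gene level, imputed).
#' @param labels class label per sample (named by sample id or aligned);
#'   `NA` samples are ignored.
#' @param labelType `"sex"` or `"tissue"`.
#' @param cfg an [mlConfig()].
#' @return a [TrainedModel-class].
#' @export
trainLabelModel <- function(se, labels, labelType = c("sex", "tissue"),
                            cfg = mlConfig()) {
  labelType <- labelType[1]
  if (labelType == "age")
    glStop("age is not predicted from expression; only sex and tissue are",
           "geolabel_ml_error")
  labelType <- match.arg(labelType)
  v <- exprsValues(se)
  labels <- alignLabels(labels, colnames(v))
  keep <- !is.na(labels)
  labels <- labels[keep]
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    glStop("training needs at least two classes", "geolabel_ml_error")
  small <- names(which(table(labels) < cfg$minClassSize))
  if (length(small))
    warning("classes below the size floor (", cfg$minClassSize, "): ",
            paste(small, collapse = ", "))
  genes <- selectFeatures(se[, keep], labels, cfg)
  x <- t(v[genes, keep, drop = FALSE])
  n <- nrow(x)
  lambda <- 1 / (n * cfg$regularizationStrength)
  weights <- matrix(0, length(genes), length(classes),
                    dimnames = list(genes, classes))
  intercepts <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    y <- as.numeric(labels == cl)
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = lambda, standardize = FALSE)
    co <- as.matrix(stats::coef(fit))
    intercepts[cl] <- co[1, 1]
    weights[, cl] <- co[-1, 1]
  }
  new("TrainedModel", labelType = labelType, classes = classes,
      selectedGenes = genes, weights = weights, intercepts = intercepts,
      trainingInfo = list(nSamples = n, seed = cfg$seed,
                          config = unclass(cfg)))
}

setMethod("show", "TrainedModel", function(object) {
  cat("TrainedModel (", object@labelType, "): ",
      length(object@classes), " classes, ",
      length(object@selectedGenes), " genes, trained on ",
      object@trainingInfo$nSamples, " samples\n", sep = "")
  invisible(object)
})

#' Predict labels from expression with a trained model
#'
#' Computes the per-class sigmoid score on the model's gene panel and
#' normalizes scores across classes to probabilities summing to one (the
#' usual one-vs-rest normalization). The argmax class is reported; exact
#' ties resolve to the first class in model order.
#'
#' @param model a [TrainedModel-class].
#' @param se expression container carrying *all* of the model's selected
#'   genes; missing genes are a named error listing them.
#' @return list with `probabilities` (samples x classes matrix) and `labels`
#'   (named character vector of argmax classes).
#' @export
predictLabels <- function(model, se) {
  v <- exprsValues(se)
  missing <- setdiff(model@selectedGenes, rownames(v))
  if (length(missing))
    glStop(paste0("expression matrix lacks model genes: ",
                  paste(missing, collapse = ", ")), "geolabel_gene_mismatch")
  x <- t(v[model@selectedGenes, , drop = FALSE])
  scores <- sweep(x %*% model@weights, 2, model@intercepts, "+")
  p <- stats::plogis(scores)
  p <- p / rowSums(p)
  lab <- model@classes[max.col(p, ties.method = "first")]
  list(probabilities = p,
       labels = stats::setNames(lab, colnames(v)))
}

#' Dummy baseline classifier
#'
#' Ignores expression entirely: each prediction is a class drawn from the
#' empirical training label distribution (seeded, reproducible), and the
#' reported probability vector is the one-hot encoding of that draw. Its
#' expected accuracy is the collision probability of the class distribution
#' and its expected AUC 0.5 — the floor any informative model must clear.
#'
#' @param labels training class labels (`NA` dropped).
#' @param seed integer seed.
#' @return an object of class `"DummyModel"`.
#' @export
dummyBaseline <- function(labels, seed = 1L) {
  labels <- labels[!is.na(labels) & labels != ""]
  if (!length(labels)) glStop("no labeled samples", "geolabel_ml_error")
  tab <- table(labels)
  structure(list(classes = names(tab),
                 proportions = as.numeric(tab) / sum(tab),
                 seed = as.integer(seed)),
            class = "DummyModel")
}

#' @rdname dummyBaseline
#' @param model a `"DummyModel"`.
#' @param sampleIds ids of the samples to predict.
#' @return `predictDummy`: same shape as [predictLabels()] output.
#' @export
predictDummy <- function(model, sampleIds) {
  n <- length(sampleIds)
  draw <- withSeed(model$seed,
                   sample(model$classes, n, replace = TRUE,
                          prob = model$proportions))
  p <- matrix(0, n, length(model$classes),
              dimnames = list(sampleIds, model$classes))
  p[cbind(seq_len(n), match(draw, model$classes))] <- 1
  list(probabilities = p, labels = stats::setNames(draw, sampleIds))
}

#' Combine a text-extracted label with an ML prediction
#'
#' Text wins whenever present (the heuristics are precision-first, so a
#' text label is never overridden); otherwise the ML argmax is accepted iff
#' its probability reaches `threshold`.
#'
#' @param textLabel a [SampleLabel-class] or `NULL`.
#' @param mlLabel predicted class (character) or `NULL`.
#' @param mlProbability probability of `mlLabel`.
#' @param threshold acceptance threshold, default 0.5.
#' @return a list `(value, source)` or `NULL` when neither stage labels the
#'   sample.
#' @export
combineLabels <- function(textLabel, mlLabel = NULL, mlProbability = NA,
                          threshold = 0.5) {
  if (!is.null(textLabel)) {
    value <- if (is(textLabel, "SexLabel")) textLabel@value
    else if (is(textLabel, "TissueLabel")) textLabel@termId
    else if (is(textLabel, "AgeLabel")) textLabel@valueYears
    else glStop("unsupported label class", "geolabel_label_error")
    return(list(value = value, source = "text",
                confidence = textLabel@confidence))
  }
  if (!is.null(mlLabel) && !is.na(mlProbability) &&
      mlProbability >= threshold)
    return(list(value = mlLabel, source = "ml",
                confidence = mlProbability))
  NULL
}

#' Serialize / deserialize a trained model as JSON
#'
#' A single self-contained JSON document: label type, classes, gene panel,
#' weights, intercepts and training metadata (including package version).
#'
#' @param model a [TrainedModel-class].
#' @param path output / input file.
#' @return `readModelJSON`: the restored [TrainedModel-class].
#' @export
writeModelJSON <- function(model, path) {
  weights <- lapply(seq_along(model@classes),
                    function(j) unname(model@weights[, j]))
  names(weights) <- model@classes
  doc <- list(labelType = model@labelType, classes = model@classes,
              selectedGenes = model@selectedGenes,
              weights = weights,
              intercepts = as.list(model@intercepts),
              trainingInfo = model@trainingInfo,
              package = list(name = "geolabel",
                             version = as.character(
                               utils::packageVersion("geolabel"))))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeModelJSON
#' @export
readModelJSON <- function(path) {
  doc <- jsonlite::fromJSON(path)
  w <- vapply(doc$classes, function(cl) as.numeric(doc$weights[[cl]]),
              numeric(length(doc$selectedGenes)))
  dimnames(w) <- list(doc$selectedGenes, doc$classes)
  new("TrainedModel", labelType = doc$labelType, classes = doc$classes,
      selectedGenes = doc$selectedGenes, weights = w,
      intercepts = stats::setNames(
        as.numeric(doc$intercepts[doc$classes]), doc$classes),
      trainingInfo = doc$trainingInfo)
}
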
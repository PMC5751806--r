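#' Experiment-stratified fold assignment
#'
#' All samples of a series (experiment) share a fold, so no experiment ever
#' contributes to both training and testing of the same fold — without this
#' a classifier can score by recognizing the experiment rather than the
#' label. Series are packed greedily: largest series first (ties shuffled
#' reproducibly under `seed`) into the currently smallest fold.
#'
#' @param seriesIds series accession per sample.
#' @param k number of folds, default 10; there must be at least `k`
#'   distinct series.
#' @param seed integer seed for tie shuffling.
#' @return a list of class `"FoldAssignment"` with `k`, `seriesFold` (named
#'   integer vector series -> fold) and `sampleFold` (per input sample).
#' @export
makeFolds <- function(seriesIds, k = 10L, seed = 1L) {
  seriesIds <- as.character(seriesIds)
  counts <- table(seriesIds)
  if (length(counts) < k)
    glStop(paste0("need at least k = ", k, " distinct series, got ",
                  length(counts)), "geolabel_cv_error")
  ord <- withSeed(seed, {
    perm <- sample(length(counts))    # random tie order
    perm[order(-as.vector(counts)[perm])]
  })
  foldSize <- numeric(k)
  seriesFold <- stats::setNames(integer(length(counts)), names(counts))
  for (i in ord) {
    f <- which.min(foldSize)
    seriesFold[names(counts)[i]] <- f
    foldSize[f] <- foldSize[f] + counts[[i]]
  }
  structure(list(k = as.integer(k), seriesFold = seriesFold,
                 sampleFold = unname(seriesFold[seriesIds]), seed = seed),
            class = "FoldAssignment")
}

#' Non-stratified (naive) fold assignment
#'
#' Assigns samples to folds at random, *ignoring* series membership — the
#' procedure experiment-stratified cross-validation exists to replace.
#' Provided for demonstrating the leakage effect: with strong series
#' signatures in the data, naive CV overestimates accuracy because the
#' classifier can recognize the experiment rather than the label.
#'
#' @param n number of samples.
#' @param k number of folds.
#' @param seed integer seed.
#' @return a `"FoldAssignment"` whose `sampleFold` ignores series.
#' @export
makeNaiveFolds <- function(n, k = 10L, seed = 1L) {
  fold <- withSeed(seed, sample(rep_len(seq_len(k), n)))
  structure(list(k = as.integer(k), seriesFold = integer(),
                 sampleFold = fold, seed = seed),
            class = "FoldAssignment")
}

#' Precision and recall for single-label predictions
#'
#' Computes per-class, micro- and macro-averaged precision and recall.
#' Abstentions (`NA` in `yPred`) count as false negatives for recall but
#' never enter a precision denominator — the convention matching a
#' precision-first extraction system. When `topM` is given the evaluation
#' is restricted to the `topM` most frequent true classes with support at
#' least `supportFloor`. With no abstentions and all classes evaluated,
#' micro precision, micro recall and accuracy coincide.
#'
#' @param yTrue,yPred equal-length character vectors; `NA` in `yPred` is an
#'   abstention.
#' @param topM optional number of most frequent true classes to keep.
#' @param supportFloor minimum true-class support (default 0; the headline
#'   evaluations of large corpora use 10).
#' @return list of class `"PrecisionRecall"`: `perClass` data frame
#'   (`class`, `support`, `tp`, `predicted`, `precision`, `recall`),
#'   `micro`, `macro` (each `c(precision, recall)`), `accuracy`,
#'   `confusion` (true x predicted table incl. an `<abstain>` column), and
#'   `nAbstained`. Undefined precisions (nothing predicted) are `NaN` and
#'   counted as 0 in the macro mean with `macroUndefined` recording how
#'   many classes that affected.
#' @export
precisionRecall <- function(yTrue, yPred, topM = NULL, supportFloor = 0L) {
  stopifnot(length(yTrue) == length(yPred))
  if (!length(yTrue)) glStop("empty evaluation input", "geolabel_eval_error")
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  support <- sort(table(yTrue), decreasing = TRUE)
  classes <- names(support)[support >= supportFloor]
  if (!is.null(topM)) classes <- utils::head(classes, topM)
  keep <- yTrue %in% classes
  yTrue <- yTrue[keep]; yPred <- yPred[keep]
  if (!length(yTrue))
    glStop("no samples left after class restriction", "geolabel_eval_error")
  predF <- factor(ifelse(is.na(yPred) | !(yPred %in% classes),
                         "<abstain>", yPred),
                  levels = c(classes, "<abstain>"))
  trueF <- factor(yTrue, levels = classes)
  confusion <- table(true = trueF, predicted = predF)
  tp <- vapply(classes, function(cl) confusion[cl, cl], 1)
  predicted <- colSums(confusion)[classes]
  supp <- rowSums(confusion)[classes]
  prec <- ifelse(predicted > 0, tp / predicted, NaN)
  rec <- tp / supp
  nAbst <- sum(confusion[, "<abstain>"])
  microPrec <- if (sum(predicted) > 0) sum(tp) / sum(predicted) else NaN
  microRec <- sum(tp) / sum(supp)
  macroPrec <- mean(ifelse(is.nan(prec), 0, prec))
  macroRec <- mean(rec)
  structure(list(
    perClass = data.frame(class = classes, support = as.vector(supp),
                          tp = as.vector(tp),
                          predicted = as.vector(predicted),
                          precision = as.vector(prec),
                          recall = as.vector(rec),
                          stringsAsFactors = FALSE),
    micro = c(precision = microPrec, recall = microRec),
    macro = c(precision = macroPrec, recall = macroRec),
    macroUndefined = sum(is.nan(prec)),
    accuracy = sum(tp) / length(yTrue),
    confusion = confusion,
    nAbstained = nAbst), class = "PrecisionRecall")
}

#' Age extraction error statistics
#'
#' Mean absolute deviation and mean squared error in years between true and
#' predicted ages, plus the fraction of predictions within one month
#' (`|error| <= 1/12` year) of the truth. Pairs with a missing prediction
#' are excluded and counted.
#'
#' @param trueYears,predYears paired nonnegative numeric vectors; `NA` in
#'   `predYears` marks a missing prediction.
#' @return list with `mad`, `mse`, `withinOneMonth`, `nUsed`, `nMissing`.
#' @export
ageError <- function(trueYears, predYears) {
  stopifnot(length(trueYears) == length(predYears))
  ok <- !is.na(predYears) & !is.na(trueYears)
  if (!any(ok))
    glStop("no age pairs with predictions to score", "geolabel_eval_error")
  d <- predYears[ok] - trueYears[ok]
  list(mad = mean(abs(d)), mse = mean(d^2),
       withinOneMonth = mean(abs(d) <= 1 / 12),
       nUsed = sum(ok), nMissing = sum(!ok))
}

#' Ontology-distance error profile
#'
#' For each (true term, predicted term) pair the undirected shortest-path
#' distance in the ontology, histogrammed next to the random-pair baseline
#' of equal size: an informative matcher's mass should sit far to the left
#' of the baseline.
#'
#' @param graph an [OntologyGraph-class].
#' @param trueTerms,predTerms paired term-id vectors; pairs containing an
#'   unknown term are skipped with a warning and counted.
#' @param nRandom size of the random baseline, default the number of scored
#'   pairs.
#' @param seed seed for the baseline draw.
#' @return list with `distances`, `random`, the two histograms as tables,
#'   and `nSkipped`.
#' @export
distanceProfile <- function(graph, trueTerms, predTerms, nRandom = NULL,
                            seed = 1L) {
  stopifnot(length(trueTerms) == length(predTerms))
  known <- trueTerms %in% graph@termIds & predTerms %in% graph@termIds &
    !is.na(trueTerms) & !is.na(predTerms)
  if (any(!known))
    warning(sum(!known), " pair(s) with unknown terms skipped")
  d <- ontologyDistance(graph, trueTerms[known], predTerms[known])
  if (is.null(nRandom)) nRandom <- max(length(d), 1L)
  r <- randomDistanceBaseline(graph, nRandom, seed = seed)
  list(distances = d, random = r,
       histogram = table(distance = d),
       randomHistogram = table(distance = r),
       nSkipped = sum(!known))
}

#' Experiment-stratified cross-validation of an expression classifier
#'
#' For each fold, feature selection and model fitting use the training
#' folds only (no leakage of the held-out experiments into the gene panel),
#' the held-out fold is predicted, and the pooled predictions are scored
#' once. A seeded dummy baseline is evaluated on the same pooled split for
#' contrast, and per-class one-vs-rest AUCs (averaged unweighted into a
#' macro AUC) are computed from the pooled probabilities.
#'
#' @param se expression container (gene level, no missing values).
#' @param labels class label per sample (named or aligned); unlabeled
#'   samples are ignored.
#' @param labelType `"sex"` or `"tissue"`.
#' @param cfg an [mlConfig()].
#' @param folds a [makeFolds()] assignment for the same samples; defaults
#'   to 10 folds built from the container's series ids.
#' @param topM,supportFloor forwarded to [precisionRecall()].
#' @return list of class `"EvaluationReport"`: `metrics`
#'   (a `"PrecisionRecall"`), `macroAUC`, `perClassAUC`, `dummy` (metrics
#'   + `macroAUC` of the baseline), `predictions` data frame, and
#'   `missingClassFolds` flagging folds whose test set contained a class
#'   absent from training.
#' @export
crossValidate <- function(se, labels, labelType = "sex", cfg = mlConfig(),
                          folds = NULL, topM = NULL, supportFloor = 0L) {
  v <- exprsValues(se)
  labels <- alignLabels(labels, colnames(v))
  keep <- which(!is.na(labels))
  se <- se[, keep]
  labels <- labels[keep]
  ser <- seriesIds(se)
  if (is.null(folds)) folds <- makeFolds(ser, k = 10L, seed = cfg$seed)
  fold <- if (length(folds$sampleFold) == length(keep)) folds$sampleFold
  else unname(folds$seriesFold[ser])
  pred <- rep(NA_character_, length(labels))
  prob <- NULL
  flagged <- integer()
  for (f in sort(unique(fold))) {
    test <- fold == f
    trainLabels <- labels[!test]
    model <- trainLabelModel(se[, !test], trainLabels, labelType, cfg)
    res <- predictLabels(model, se[, test])
    pred[test] <- res$labels
    if (length(setdiff(unique(labels[test]), model@classes)))
      flagged <- c(flagged, f)
    p <- res$probabilities
    if (is.null(prob)) {
      prob <- matrix(NA_real_, length(labels), ncol(p),
                     dimnames = list(colnames(v)[keep], colnames(p)))
    }
    common <- intersect(colnames(prob), colnames(p))
    prob[test, common] <- p[, common]
  }
  metrics <- precisionRecall(labels, pred, topM = topM,
                             supportFloor = supportFloor)
  perClassAUC <- vapply(colnames(prob), function(cl) {
    y <- as.integer(labels == cl)
    pr <- prob[, cl]
    ok <- !is.na(pr)
    if (length(unique(y[ok])) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(y[ok], pr[ok], quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, 1)
  dummyPred <- rep(NA_character_, length(labels))
  dummyProb <- NULL
  for (f in sort(unique(fold))) {
    test <- fold == f
    dm <- dummyBaseline(labels[!test], seed = cfg$seed + f)
    dres <- predictDummy(dm, colnames(v)[keep][test])
    dummyPred[test] <- dres$labels
    if (is.null(dummyProb))
      dummyProb <- matrix(0, length(labels), length(unique(labels)),
                          dimnames = list(NULL, sort(unique(labels))))
    common <- intersect(colnames(dummyProb), colnames(dres$probabilities))
    dummyProb[test, common] <- dres$probabilities[, common]
  }
  ## tiny seeded jitter breaks the all-ties degeneracy of one-hot scores so
  ## the dummy AUC is an honest draw around 0.5 rather than exactly 0.5
  dummyProb <- dummyProb + withSeed(cfg$seed,
    matrix(stats::runif(length(dummyProb), 0, 1e-6), nrow(dummyProb)))
  dummyAUC <- vapply(colnames(dummyProb), function(cl) {
    y <- as.integer(labels == cl)
    if (length(unique(y)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(y, dummyProb[, cl], quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, 1)
  structure(list(
    metrics = metrics,
    macroAUC = mean(perClassAUC, na.rm = TRUE),
    perClassAUC = perClassAUC,
    dummy = list(metrics = precisionRecall(labels, dummyPred, topM = topM,
                                           supportFloor = supportFloor),
                 macroAUC = mean(dummyAUC, na.rm = TRUE)),
    predictions = data.frame(sample_id = colnames(v)[keep],
                             series_id = ser, fold = fold,
                             true = labels, predicted = pred,
                             stringsAsFactors = FALSE),
    missingClassFolds = flagged,
    folds = folds), class = "EvaluationReport")
}

#' Serialize an evaluation report
#'
#' Writes `report.json` (all scalar metrics), `confusion.tsv` and, when
#' distance histograms are attached, `distance_histogram.tsv` (columns
#' `bin`, `count`, `random_count`) under `dir`, plus a human-readable
#' `report.txt`.
#'
#' @param report an `"EvaluationReport"` (or a `"PrecisionRecall"`).
#' @param dir output directory, created if needed.
#' @param profile optional [distanceProfile()] result.
#' @export
writeReport <- function(report, dir, profile = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- if (inherits(report, "EvaluationReport"))
    report$metrics else report
  doc <- list(micro = as.list(metrics$micro),
              macro = as.list(metrics$macro),
              accuracy = metrics$accuracy,
              nAbstained = metrics$nAbstained,
              perClass = metrics$perClass)
  if (inherits(report, "EvaluationReport")) {
    doc$macroAUC <- report$macroAUC
    doc$dummy <- list(macro = as.list(report$dummy$metrics$macro),
                      macroAUC = report$dummy$macroAUC)
  }
  jsonlite::write_json(doc, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.table(as.data.frame.matrix(metrics$confusion),
                     file.path(dir, "confusion.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  if (!is.null(profile)) {
    bins <- sort(unique(c(as.numeric(names(profile$histogram)),
                          as.numeric(names(profile$randomHistogram)))))
    hist <- data.frame(
      bin = bins,
      count = as.integer(profile$histogram[as.character(bins)]),
      random_count = as.integer(profile$randomHistogram[as.character(bins)]))
    hist[is.na(hist)] <- 0L
    utils::write.table(hist, file.path(dir, "distance_histogram.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  txt <- c(sprintf("micro P/R: %.4f / %.4f", metrics$micro["precision"],
                   metrics$micro["recall"]),
           sprintf("macro P/R: %.4f / %.4f", metrics$macro["precision"],
                   metrics$macro["recall"]),
           sprintf("accuracy: %.4f  (abstained: %d)", metrics$accuracy,
                   metrics$nAbstained))
  if (inherits(report, "EvaluationReport"))
    txt <- c(txt, sprintf("macro AUC: %.4f (dummy %.4f)", report$macroAUC,
                          report$dummy$macroAUC))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
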
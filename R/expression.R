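#' Build an expression matrix container
#'
#' Expression data are held in a [SummarizedExperiment::SummarizedExperiment]
#' with one assay `"exprs"` (features x samples, log scale), sample and
#' series accessions in `colData`, and an `isGeneLevel` flag in `metadata`.
#'
#' @param values numeric matrix, features x samples.
#' @param featureIds feature (probe or gene) ids; default rownames.
#' @param sampleIds sample accessions; default colnames, must be unique.
#' @param seriesIds series accession per sample (recycled if length 1).
#' @param isGeneLevel logical flag; `FALSE` for probe-level data.
#' @return a `SummarizedExperiment`.
#' @export
expressionMatrix <- function(values, featureIds = rownames(values),
                             sampleIds = colnames(values),
                             seriesIds = "", isGeneLevel = FALSE) {
  values <- as.matrix(values)
  if (is.null(featureIds) || is.null(sampleIds))
    glStop("feature and sample ids are required", "geolabel_expr_error")
  if (anyDuplicated(sampleIds))
    glStop("duplicate sample ids in expression matrix",
           "geolabel_expr_error")
  stopifnot(length(featureIds) == nrow(values),
            length(sampleIds) == ncol(values))
  seriesIds <- rep_len(as.character(seriesIds), ncol(values))
  dimnames(values) <- list(featureIds, sampleIds)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(sample_id = sampleIds,
                                   series_id = seriesIds,
                                   row.names = sampleIds),
    metadata = list(isGeneLevel = isGeneLevel))
}

#' @describeIn expressionMatrix the expression values matrix
#' @param se a `SummarizedExperiment` built by `expressionMatrix()`
#' @export
exprsValues <- function(se) SummarizedExperiment::assay(se, "exprs")

#' @describeIn expressionMatrix series accessions aligned to samples
#' @export
seriesIds <- function(se) {
  as.character(SummarizedExperiment::colData(se)$series_id)
}

#' Read an expression matrix from TSV or MatrixMarket
#'
#' TSV layout: header row of sample ids, first column feature ids. MTX input
#' takes the triplet file plus sidecar row/column id files (one id per
#' line, conventional `*.rownames` / `*.colnames` suffixes unless given).
#'
#' @param path matrix file.
#' @param format `"auto"` (by extension), `"tsv"` or `"mtx"`.
#' @param rowIdPath,colIdPath id sidecars for MTX input.
#' @param seriesIds optional series accession per sample.
#' @return a `SummarizedExperiment` (see [expressionMatrix()]).
#' @export
readExpression <- function(path, format = c("auto", "tsv", "mtx"),
                           rowIdPath = NULL, colIdPath = NULL,
                           seriesIds = "") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, na.strings = c("NA", ""))
    vals <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    expressionMatrix(vals, featureIds = as.character(df[[1]]),
                     sampleIds = colnames(df)[-1], seriesIds = seriesIds)
  } else {
    if (is.null(rowIdPath)) rowIdPath <- paste0(path, ".rownames")
    if (is.null(colIdPath)) colIdPath <- paste0(path, ".colnames")
    vals <- as.matrix(Matrix::readMM(path))
    expressionMatrix(vals, featureIds = readLines(rowIdPath),
                     sampleIds = readLines(colIdPath), seriesIds = seriesIds)
  }
}

#' Read a probe-to-gene map
#'
#' Two-column TSV (`probe_id`, `gene_id`, header optional in that order).
#'
#' @param path file path.
#' @return named character vector: names are probe ids, values gene ids.
#' @export
readProbeGeneMap <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("probe_id", "gene_id") %in% names(df)))
    names(df)[1:2] <- c("probe_id", "gene_id")
  stats::setNames(df$gene_id, df$probe_id)
}

#' Log-transform an expression matrix if it looks linear-scale
#'
#' Heuristic used on arbitrary downloaded matrices: when the maximum value
#' exceeds `threshold` (default 30, far above any log2 microarray
#' intensity), the matrix is assumed linear-scale and `log2(x + 1)` is
#' applied; otherwise it is returned unchanged. Override with `force`.
#'
#' @param se expression container.
#' @param threshold decision threshold on the matrix maximum.
#' @param force `TRUE`/`FALSE` to force/suppress the transform, `NA` (the
#'   default) to apply the heuristic.
#' @return the (possibly transformed) container.
#' @export
ensureLogScale <- function(se, threshold = 30, force = NA) {
  v <- exprsValues(se)
  apply_ <- if (is.na(force)) max(v, na.rm = TRUE) > threshold else force
  if (apply_) {
    SummarizedExperiment::assay(se, "exprs") <- log2(v + 1)
  }
  se
}

#' Collapse probe-level rows to gene level
#'
#' For every gene the probe with the highest mean expression across samples
#' is chosen and its row copied; mean ties are broken by the
#' lexicographically smallest probe id. Probes absent from the map are
#' dropped (the count is reported in a message).
#'
#' @param se probe-level expression container.
#' @param map named character vector probe id -> gene id
#'   (see [readProbeGeneMap()]).
#' @return a gene-level `SummarizedExperiment`.
#' @export
collapseProbes <- function(se, map) {
  v <- exprsValues(se)
  probes <- intersect(rownames(v), names(map))
  if (!length(probes))
    glStop("no probes of the matrix are covered by the probe-gene map",
           "geolabel_expr_error")
  dropped <- nrow(v) - length(probes)
  if (dropped > 0)
    message(dropped, " probe(s) absent from the map were dropped")
  means <- rowMeans(v[probes, , drop = FALSE], na.rm = TRUE)
  genes <- map[probes]
  ord <- order(genes, -means, probes)   # per gene: max mean, then smallest id
  pick <- probes[ord][!duplicated(genes[ord])]
  geneIds <- unname(genes[pick])
  out <- v[pick, , drop = FALSE]
  rownames(out) <- geneIds
  res <- expressionMatrix(out[order(geneIds), , drop = FALSE],
                          sampleIds = colnames(v),
                          seriesIds = seriesIds(se), isGeneLevel = TRUE)
  res
}

#' Quantile-normalize samples of an expression matrix
#'
#' Classic between-array quantile normalization (via
#' [limma::normalizeQuantiles] with tie averaging): after the operation the
#' sorted value vector of every sample is identical.
#'
#' @param se expression container without missing values.
#' @return the normalized container.
#' @export
quantileNormalize <- function(se) {
  v <- exprsValues(se)
  if (ncol(v) < 2) {
    warning("quantile normalization needs >= 2 samples; returning input")
    return(se)
  }
  nv <- limma::normalizeQuantiles(v, ties = TRUE)
  dimnames(nv) <- dimnames(v)
  SummarizedExperiment::assay(se, "exprs") <- nv
  se
}

#' Impute missing values by k-nearest-neighbor samples
#'
#' Each missing entry (gene g, sample s) is replaced by the mean of g's
#' values in the `k` samples nearest to s — Euclidean distance computed over
#' the genes both samples observe, scaled to per-gene units so unequal
#' overlap does not bias the ranking — restricted to neighbors that observe
#' g. If no neighbor observes g the gene's global mean is used. Genes
#' missing everywhere are dropped with a warning.
#'
#' @param se expression container.
#' @param k number of neighbor samples, default 5.
#' @return the imputed container (no missing values remain).
#' @export
knnImpute <- function(se, k = 5L) {
  v <- exprsValues(se)
  if (!anyNA(v)) return(se)
  allMissing <- rowSums(!is.na(v)) == 0L
  if (any(allMissing)) {
    warning(sum(allMissing), " gene(s) with no observed values dropped")
    v <- v[!allMissing, , drop = FALSE]
  }
  obs <- !is.na(v)
  geneMeans <- rowMeans(v, na.rm = TRUE)
  needs <- which(colSums(!obs) > 0L)
  n <- ncol(v)
  for (s in needs) {
    shared <- obs[, s] & obs              # genes observed in both
    sq <- (v[, s] - v)^2
    sq[!shared] <- NA
    d <- sqrt(colMeans(sq, na.rm = TRUE)) # per-gene-scaled distance
    d[s] <- Inf
    d[colSums(shared) == 0L] <- Inf
    ord <- order(d)
    for (g in which(!obs[, s])) {
      nb <- ord[obs[g, ord] & is.finite(d[ord])]
      nb <- nb[seq_len(min(k, length(nb)))]
      v[g, s] <- if (length(nb)) mean(v[g, nb]) else geneMeans[g]
    }
  }
  out <- expressionMatrix(v, sampleIds = colnames(v),
                          seriesIds = seriesIds(se),
                          isGeneLevel = isTRUE(
                            S4Vectors::metadata(se)$isGeneLevel))
  out
}

#' The full normalization chain
#'
#' Log-scale check, probe collapse (when a map is given and the data are
#' probe-level), quantile normalization, then KNN imputation — the standard
#' preprocessing applied before training or prediction. On clean gene-level
#' data the chain is idempotent.
#'
#' @param se expression container.
#' @param map optional probe-gene map.
#' @param knnK imputation neighbors, default 5.
#' @return the processed gene-level container.
#' @export
normalizeExpression <- function(se, map = NULL, knnK = 5L) {
  se <- ensureLogScale(se)
  if (!is.null(map) && !isTRUE(S4Vectors::metadata(se)$isGeneLevel))
    se <- collapseProbes(se, map)
  se <- quantileNormalize(se)
  knnImpute(se, k = knnK)
}
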
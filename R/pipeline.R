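#' Run the text extractors over a metadata corpus
#'
#' Applies the requested extractors to every sample and keeps an extraction
#' log with one row per (sample, label type) attempt, including misses with
#' a reason code (`no_match`, `error`). The per-label coverage fraction —
#' the share of samples whose text yields the label — is attached, the
#' number the ML fallback stage exists to improve on.
#'
#' @param metas list of [SampleMetadata-class] objects.
#' @param labelTypes subset of `c("sex", "age", "tissue")`.
#' @param graph an [OntologyGraph-class]; required for tissue.
#' @param order a [fieldOrder()].
#' @param ageCfg an [ageConfig()].
#' @param matcherCfg a [matcherConfig()].
#' @param aggressive forwarded to [extractSex()].
#' @return list with `labels` (list of [SampleLabel-class]), `log` (data
#'   frame `sample_id`, `label_type`, `status`, `reason`), and `coverage`
#'   (named fractions).
#' @export
extractAll <- function(metas, labelTypes = c("sex", "age", "tissue"),
                       graph = NULL, order = fieldOrder(),
                       ageCfg = ageConfig(), matcherCfg = matcherConfig(),
                       aggressive = FALSE) {
  labelTypes <- match.arg(labelTypes, several.ok = TRUE)
  matcher <- NULL
  if ("tissue" %in% labelTypes) {
    if (is.null(graph))
      glStop("tissue extraction requires an ontology", "geolabel_cli_error")
    matcher <- buildMatcher(graph, matcherCfg)
  }
  labels <- list()
  logRows <- list()
  for (m in metas) {
    for (lt in labelTypes) {
      lab <- withCallingHandlers(
        tryCatch(switch(lt,
          sex = extractSex(m, order, aggressive = aggressive),
          age = extractAge(m, order, ageCfg),
          tissue = matchTissue(m, order, matcher, graph)),
          error = function(e) structure(conditionMessage(e),
                                        class = "extraction_error")),
        warning = function(w) invokeRestart("muffleWarning"))
      status <- if (inherits(lab, "extraction_error")) "error"
      else if (is.null(lab)) "miss" else "hit"
      logRows[[length(logRows) + 1L]] <- data.frame(
        sample_id = m@sampleId, label_type = lt, status = status,
        reason = if (status == "error") unclass(lab)[1]
        else if (status == "miss") "no_match" else "",
        stringsAsFactors = FALSE)
      if (status == "hit") labels[[length(labels) + 1L]] <- lab
    }
  }
  log <- do.call(rbind, logRows)
  coverage <- vapply(labelTypes, function(lt) {
    sub <- log[log$label_type == lt, ]
    mean(sub$status == "hit")
  }, 1)
  list(labels = labels, log = log, coverage = coverage)
}
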
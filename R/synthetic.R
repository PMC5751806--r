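## Synthetic fixtures: metadata corpora with planted labels, toy ontologies,
## and expression matrices with label-informative genes. Everything is
## reproducible under a single seed and each generator returns the exact
## ground truth needed to score the extractors and classifiers against it.

#' Specification of a synthetic metadata corpus
#'
#' The defaults encode the observed make-up of real GEO metadata: sex is
#' present in the text of 26% of samples, age in 21%, tissue in 86%, and
#' ages follow the gold-standard profile (mean 46.7, sd 21.6 years,
#' truncated to `[0, 95]`). Phrasing templates cover the pattern families
#' seen in practice — explicit key-value, abbreviated, numeric-coded,
#' unit-in-key, bare number, misspelled unit, implicit parenthetical, and a
#' derived-adjective tissue form — including the families a precision-first
#' extractor must *not* fire on.
#'
#' Real experiments also impose structure on the labels themselves: many
#' series are single-sex cohorts and most study one tissue. The generator
#' reproduces both (`sexSeriesBias`, `tissueConcentration`), which is what
#' makes experiment-stratified cross-validation behave differently from
#' naive cross-validation on these corpora, as it does on real data.
#'
#' @param nSamples,nSeries corpus size; samples are spread over series
#'   round-robin.
#' @param labelPresence named fractions of samples whose text encodes each
#'   label.
#' @param phrasingWeights named list of per-label template weight vectors;
#'   see defaults for the template names.
#' @param ageMeanSd mean and sd (years) of the truncated-normal age model.
#' @param sexSeriesBias fraction of series that are single-sex cohorts.
#' @param tissueConcentration probability a sample carries its series'
#'   dominant tissue rather than a random one.
#' @param seed integer seed.
#' @return list of class `"CorpusSpec"`.
#' @export
corpusSpec <- function(nSamples = 200L, nSeries = 20L,
                       labelPresence = c(sex = 0.26, age = 0.21,
                                         tissue = 0.86),
                       phrasingWeights = list(
                         sex = c(explicit = 0.5, abbreviated = 0.25,
                                 numeric = 0.15, implicit = 0.1),
                         age = c(keyvalue_unit = 0.45, unit_in_key = 0.2,
                                 bare = 0.2, misspelled_unit = 0.1,
                                 implicit = 0.05),
                         tissue = c(characteristics = 0.6,
                                    source_name = 0.25, freetext = 0.1,
                                    derived_adjective = 0.05)),
                       ageMeanSd = c(46.7, 21.6), sexSeriesBias = 0.5,
                       tissueConcentration = 0.8, seed = 1L) {
  stopifnot(all(labelPresence >= 0 & labelPresence <= 1),
            all(c("sex", "age", "tissue") %in% names(labelPresence)))
  structure(list(nSamples = as.integer(nSamples),
                 nSeries = as.integer(nSeries),
                 labelPresence = labelPresence,
                 phrasingWeights = phrasingWeights,
                 ageMeanSd = ageMeanSd, sexSeriesBias = sexSeriesBias,
                 tissueConcentration = tissueConcentration,
                 seed = as.integer(seed)),
            class = "CorpusSpec")
}

#' Specification of a synthetic expression matrix
#'
#' @param nGenes total genes; `nInformative` of them per predictable label
#'   carry a class-dependent mean shift of `effectSize` (log2 units).
#' @param nInformative informative genes per label type.
#' @param effectSize mean shift (log2 units) separating the classes on an
#'   informative gene.
#' @param noiseSd per-measurement Gaussian noise sd (log2 units).
#' @param seriesSd sd of per-series, per-gene random intercepts; nonzero
#'   values make samples of one experiment resemble each other, which is
#'   exactly what experiment-stratified cross-validation must guard
#'   against.
#' @param missingRate fraction of entries set missing, in `[0, 0.5)`.
#' @param seed integer seed.
#' @return list of class `"ExpressionSpec"`.
#' @export
expressionSpec <- function(nGenes = 2000L, nInformative = 20L,
                           effectSize = 1.0, noiseSd = 1.0,
                           seriesSd = 0.5, missingRate = 0, seed = 1L) {
  stopifnot(nInformative < nGenes, missingRate >= 0, missingRate < 0.5)
  structure(list(nGenes = as.integer(nGenes),
                 nInformative = as.integer(nInformative),
                 effectSize = effectSize, noiseSd = noiseSd,
                 seriesSd = seriesSd, missingRate = missingRate,
                 seed = as.integer(seed)),
            class = "ExpressionSpec")
}

## Pronounceable unique nonsense words for toy term names/synonyms.
.makeWords <- function(n, minSyllables = 3L) {
  syll <- c("ba", "re", "mo", "ta", "lu", "ni", "sor", "ke", "vi", "pa",
            "do", "zu", "fen", "gal", "mir", "qua", "hel", "tis", "ron",
            "ny")
  words <- character(0)
  while (length(words) < n) {
    w <- paste(sample(syll, minSyllables + stats::rbinom(1, 2, 0.4),
                      replace = TRUE), collapse = "")
    if (!w %in% words) words <- c(words, w)
  }
  words
}

#' Generate a synthetic metadata corpus with known labels
#'
#' Every sample gets a true sex, age and tissue; each label is *encoded* in
#' the text only when sampled present, using a template drawn from the
#' spec's phrasing weights. The returned truth table records, per sample
#' and label, the truth, the template used, and whether a precision-first
#' extractor is expected to emit a label (`*_expected`) — implicit and
#' derived-adjective templates are planted specifically so the extractors
#' do **not** fire on them, and the misspelled-unit age template is
#' expected to fire with a wrong, default-unit value unless the bound
#' discards it.
#'
#' @param spec a [corpusSpec()].
#' @param graph an [OntologyGraph-class] providing the tissue vocabulary
#'   (non-obsolete, non-root terms are sampled).
#' @return list with `metadata` (list of [SampleMetadata-class]) and
#'   `truth` (data frame).
#' @export
genMetadata <- function(spec, graph) {
  candidates <- which(!graph@obsolete & graph@depths > 0L)
  if (!length(candidates)) candidates <- which(!graph@obsolete)
  withSeed(spec$seed, {
    n <- spec$nSamples
    sampleIds <- sprintf("GSM%06d", seq_len(n))
    series <- sprintf("GSE%04d", (seq_len(n) - 1L) %% spec$nSeries + 1L)
    seriesNames <- unique(series)
    ## single-sex cohorts and per-series dominant tissues
    singleSex <- stats::runif(length(seriesNames)) < spec$sexSeriesBias
    cohortSex <- sample(c("male", "female"), length(seriesNames),
                        replace = TRUE)
    names(singleSex) <- names(cohortSex) <- seriesNames
    sex <- ifelse(singleSex[series], cohortSex[series],
                  sample(c("male", "female"), n, replace = TRUE))
    age <- pmin(pmax(stats::rnorm(n, spec$ageMeanSd[1], spec$ageMeanSd[2]),
                     0), 95)
    dominant <- stats::setNames(
      sample(candidates, length(seriesNames), replace = TRUE), seriesNames)
    tissueIdx <- ifelse(stats::runif(n) < spec$tissueConcentration,
                        dominant[series],
                        sample(candidates, n, replace = TRUE))
    tissue <- graph@termIds[tissueIdx]
    tissueName <- graph@termNames[tissueIdx]
    pres <- function(lbl) stats::runif(n) < spec$labelPresence[[lbl]]
    tmpl <- function(lbl, present) {
      w <- spec$phrasingWeights[[lbl]]
      out <- rep(NA_character_, n)
      out[present] <- sample(names(w), sum(present), replace = TRUE,
                             prob = w)
      out
    }
    sexPresent <- pres("sex"); agePresent <- pres("age")
    tissuePresent <- pres("tissue")
    sexTmpl <- tmpl("sex", sexPresent)
    ageTmpl <- tmpl("age", agePresent)
    tissueTmpl <- tmpl("tissue", tissuePresent)
    ageUnit <- sample(c("years", "months", "weeks", "days"), n,
                      replace = TRUE, prob = c(0.7, 0.15, 0.1, 0.05))
    sexKeys <- sample(c("Sex", "sex", "Gender", "gender"), n, replace = TRUE)
    ageKeys <- sample(c("Age", "age"), n, replace = TRUE)
    tisKeys <- sample(c("Tissue", "tissue", "Organ", "Cell type"), n,
                      replace = TRUE)
    unitTok <- c(years = "y", months = "mo", weeks = "wk", days = "days")
    metas <- vector("list", n)
    expSex <- logical(n); expAge <- logical(n); expTissue <- logical(n)
    expAgeYears <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      chars <- character(); desc <- character(); src <- "not specified"
      title <- sprintf("sample %d expression profile", i)
      sexTok <- if (sex[i] == "male") c("male", "M", "1") else
        c("female", "F", "0")
      if (isTRUE(sexPresent[i])) switch(sexTmpl[i],
        explicit = { chars <- c(chars, paste0(sexKeys[i], ": ", sexTok[1]))
                     expSex[i] <- TRUE },
        abbreviated = { desc <- c(desc, paste0("sex: ", sexTok[2]))
                        expSex[i] <- TRUE },
        numeric = { chars <- c(chars, paste0(sexKeys[i], ": ", sexTok[3]))
                    expSex[i] <- TRUE },
        implicit = { title <- sprintf("patient %d (%d, %s, non-smoker)", i,
                                      round(age[i]), sexTok[2]) })
      if (isTRUE(agePresent[i])) {
        u <- ageUnit[i]
        inUnit <- round(age[i] / c(years = 1, months = 1 / 12,
                                   weeks = 7 / 365.25,
                                   days = 1 / 365.25)[[u]], 1)
        switch(ageTmpl[i],
          keyvalue_unit = {
            chars <- c(chars, paste0(ageKeys[i], ": ", inUnit, " ",
                                     unitTok[[u]]))
            expAge[i] <- TRUE
            expAgeYears[i] <- convertAge(inUnit, u)
          },
          unit_in_key = {
            chars <- c(chars, paste0("age (", unitTok[[u]], "): ", inUnit))
            expAge[i] <- TRUE
            expAgeYears[i] <- convertAge(inUnit, u)
          },
          bare = {
            yrs <- round(age[i], 1)
            chars <- c(chars, paste0(ageKeys[i], ": ", yrs))
            expAge[i] <- TRUE
            expAgeYears[i] <- yrs
          },
          misspelled_unit = {
            mis <- c(years = "yesr", months = "monhts", weeks = "weeeks",
                     days = "dsay")[[u]]
            chars <- c(chars, paste0(ageKeys[i], ": ", inUnit, " ", mis))
            ## extractor falls back to the species default (years): the
            ## label appears, with a wrong value, unless the bound kills it
            if (inUnit <= 120) {
              expAge[i] <- TRUE
              expAgeYears[i] <- inUnit
            }
          },
          implicit = {
            title <- sprintf("patient %d (%d, %s)", i, round(age[i]),
                             toupper(substr(sex[i], 1, 1)))
          })
      }
      if (isTRUE(tissuePresent[i])) switch(tissueTmpl[i],
        characteristics = {
          chars <- c(chars, paste0(tisKeys[i], ": ", tissueName[i]))
          expTissue[i] <- TRUE },
        source_name = { src <- paste0(tissueName[i], " specimen")
                        expTissue[i] <- TRUE },
        freetext = {
          title <- sprintf("expression profiling of %s samples",
                           tissueName[i])
          expTissue[i] <- TRUE },
        derived_adjective = {
          desc <- c(desc, paste0(tissueName[i], "al biopsy material")) })
      metas[[i]] <- sampleMetadata(
        sampleIds[i], seriesId = series[i], platformId = "GPL0000",
        organism = "Homo sapiens", molecule = "total RNA", title = title,
        description = paste(desc, collapse = "; "),
        sourceName = c(`1` = src),
        characteristics = c(`1` = paste(chars, collapse = "; ")))
    }
    truth <- data.frame(
      sample_id = sampleIds, series_id = series,
      sex = sex, sex_present = sexPresent, sex_template = sexTmpl,
      sex_expected = expSex,
      age_years = age, age_present = agePresent, age_template = ageTmpl,
      age_expected = expAge, age_expected_years = expAgeYears,
      tissue_id = tissue, tissue_present = tissuePresent,
      tissue_template = tissueTmpl, tissue_expected = expTissue,
      stringsAsFactors = FALSE)
    list(metadata = metas, truth = truth)
  })
}

#' Generate a toy ontology DAG
#'
#' Builds a rooted DAG of invented term names with synonyms and occasional
#' double-parent diamonds. The generator computes every term's depth by its
#' own incremental rule (`min(parent depths) + 1`, terms created in
#' topological order) and returns them as the `generatorDepths` attribute —
#' an independent check on [termDepth()].
#'
#' @param nTerms number of terms (>= 1).
#' @param branching mean number of children per internal node (controls
#'   parent sampling bias toward recent terms).
#' @param nSynonyms synonyms per term.
#' @param diamondProb probability a non-root term gets a second parent.
#' @param seed integer seed.
#' @return an [OntologyGraph-class] with attribute `generatorDepths`.
#' @export
genToyOntology <- function(nTerms = 30L, branching = 3L, nSynonyms = 2L,
                           diamondProb = 0.2, seed = 1L) {
  stopifnot(nTerms >= 1)
  withSeed(seed, {
    ids <- sprintf("TOY:%07d", seq_len(nTerms))
    words <- .makeWords(nTerms * (1L + nSynonyms))
    names <- words[seq_len(nTerms)]
    synWords <- words[-seq_len(nTerms)]
    parents <- vector("list", nTerms)
    depths <- integer(nTerms)
    for (i in seq_len(nTerms)) {
      if (i == 1L) { parents[[i]] <- character(); depths[i] <- 0L; next }
      ## bias toward recent terms so depth grows with nTerms/branching
      w <- seq_len(i - 1L)^(branching / 2)
      p1 <- sample.int(i - 1L, 1L, prob = w)
      ps <- ids[p1]
      if (i > 2L && stats::runif(1) < diamondProb) {
        p2 <- sample(setdiff(seq_len(i - 1L), p1), 1L)
        ps <- c(ps, ids[p2])
      }
      parents[[i]] <- ps
      depths[i] <- min(depths[match(ps, ids)]) + 1L
    }
    synonyms <- lapply(seq_len(nTerms), function(i) {
      if (!nSynonyms) return(data.frame(text = character(),
                                        scope = character(),
                                        stringsAsFactors = FALSE))
      idx <- (i - 1L) * nSynonyms + seq_len(nSynonyms)
      data.frame(text = synWords[idx],
                 scope = sample(c("EXACT", "RELATED", "NARROW", "BROAD"),
                                nSynonyms, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    g <- ontologyGraph(ids, names, synonyms, parents,
                       rep(FALSE, nTerms))
    attr(g, "generatorDepths") <- stats::setNames(depths, ids)
    g
  })
}

#' Generate a synthetic expression matrix with planted label signal
#'
#' Log-scale Gaussian intensities: per-gene baseline means around 7,
#' per-series per-gene random intercepts (sd `seriesSd`) so samples of one
#' experiment are correlated, a class-dependent shift of `effectSize` on
#' the informative genes of each label, i.i.d. noise, and optional missing
#' entries. Sex uses a symmetric +/- `effectSize`/2 shift on its
#' informative genes; each tissue class gets its own disjoint block of
#' informative genes shifted by `effectSize`.
#'
#' @param spec an [expressionSpec()].
#' @param truth a [genMetadata()] truth table (columns `sample_id`,
#'   `series_id`, `sex`, `tissue_id` are used).
#' @return a `SummarizedExperiment` (see [expressionMatrix()]); the
#'   informative gene sets are in `metadata(se)$informativeGenes`.
#' @export
genExpression <- function(spec, truth) {
  withSeed(spec$seed, {
    n <- nrow(truth); G <- spec$nGenes
    genes <- sprintf("GENE%05d", seq_len(G))
    sexGenes <- genes[seq_len(spec$nInformative)]
    tissues <- sort(unique(truth$tissue_id))
    tissueGenes <- list()
    offset <- spec$nInformative
    for (tt in tissues) {
      idx <- offset + seq_len(spec$nInformative)
      if (max(idx) > G) glStop("nGenes too small for informative blocks",
                               "geolabel_synth_error")
      tissueGenes[[tt]] <- genes[idx]
      offset <- max(idx)
    }
    mu <- stats::rnorm(G, 7, 0.5)
    series <- unique(truth$series_id)
    seriesEff <- matrix(stats::rnorm(G * length(series), 0, spec$seriesSd),
                        G, length(series), dimnames = list(genes, series))
    v <- matrix(mu, G, n) + seriesEff[, truth$series_id] +
      matrix(stats::rnorm(G * n, 0, spec$noiseSd), G, n)
    sexShift <- ifelse(truth$sex == "male", spec$effectSize / 2,
                       -spec$effectSize / 2)
    v[seq_len(spec$nInformative), ] <-
      v[seq_len(spec$nInformative), ] + rep(sexShift, each = spec$nInformative)
    for (tt in tissues) {
      cols <- which(truth$tissue_id == tt)
      rows <- match(tissueGenes[[tt]], genes)
      v[rows, cols] <- v[rows, cols] + spec$effectSize
    }
    if (spec$missingRate > 0) {
      nMiss <- round(spec$missingRate * length(v))
      v[sample(length(v), nMiss)] <- NA
    }
    se <- expressionMatrix(v, featureIds = genes,
                           sampleIds = truth$sample_id,
                           seriesIds = truth$series_id, isGeneLevel = TRUE)
    S4Vectors::metadata(se)$informativeGenes <-
      c(list(sex = sexGenes), tissueGenes)
    se
  })
}
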
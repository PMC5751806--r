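## Text-heuristic extraction of sex and age.
##
## Both extractors search a sample's fields in the canonical order (see
## fieldOrder()) and stop at the first field class that yields a label; the
## parsed Characteristics pairs are inspected first, with pairs whose key
## names the attribute (e.g. "sex", "age (mo)") taking priority within them.
## This is deliberately precision-first: patterns only fire on explicit
## "key: value" style annotations unless the opt-in aggressive mode is on.

.geolabelCache <- new.env(parent = emptyenv())

#' The shipped extraction pattern table
#'
#' A versioned plain-text TSV (columns `pattern`, `label_type`, `value`,
#' `confidence`, `keyed_only`) holding the sex value vocabulary and the age
#' unit synonym table. Curators can extend the vocabulary without code
#' changes by passing their own table to the extractors. `keyed_only`
#' restricts a pattern (the 0/1 numeric sex coding) to values of pairs whose
#' key explicitly names the attribute.
#'
#' @param path optional path to an alternative TSV.
#' @return the pattern table as a data frame.
#' @export
defaultPatternTable <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.geolabelCache$patterns)) return(.geolabelCache$patterns)
    path <- system.file("extdata", "label_patterns.tsv", package = "geolabel")
  }
  tab <- utils::read.delim(path, colClasses = "character")
  tab$confidence <- as.numeric(tab$confidence)
  tab$keyed_only <- as.logical(tab$keyed_only)
  .geolabelCache$patterns <- tab
  tab
}

sexVocabulary <- function(patterns = defaultPatternTable()) {
  patterns[patterns$label_type == "sex", , drop = FALSE]
}

unitSynonyms <- function(patterns = defaultPatternTable()) {
  u <- patterns[patterns$label_type == "age_unit", , drop = FALSE]
  stats::setNames(u$value, u$pattern)
}

#' Age extraction configuration
#'
#' @param plausibleRangeYears two numbers `(min, max)`; extracted ages whose
#'   canonical value in years falls outside this closed interval are
#'   discarded with a warning. Default `c(0, 120)` for human data (0 kept
#'   inclusive so neonates survive).
#' @param speciesDefaultUnit named character vector mapping a species class
#'   to the unit assumed when the text carries a number but no unit:
#'   `human -> years`, `rodent -> months`.
#' @param unitSynonymTable named character vector token -> canonical unit;
#'   defaults to the shipped pattern table.
#' @return a list with class `"AgeConfig"`.
#' @export
ageConfig <- function(plausibleRangeYears = c(0, 120),
                      speciesDefaultUnit = c(human = "years",
                                             rodent = "months"),
                      unitSynonymTable = unitSynonyms()) {
  stopifnot(length(plausibleRangeYears) == 2,
            plausibleRangeYears[1] <= plausibleRangeYears[2])
  structure(list(plausibleRangeYears = plausibleRangeYears,
                 speciesDefaultUnit = speciesDefaultUnit,
                 unitSynonymTable = unitSynonymTable),
            class = "AgeConfig")
}

## Rodents are recognized by genus substring in the organism field; anything
## else (including an empty field) defaults to human.
speciesDefaultUnit <- function(organismText, cfg = ageConfig()) {
  o <- tolower(organismText)
  if (grepl("mus|rattus", o)) cfg$speciesDefaultUnit[["rodent"]]
  else cfg$speciesDefaultUnit[["human"]]
}

#' Convert an age to years
#'
#' Conversion constants: 1 year = 12 months = 365.25 days; a week is 7 days.
#'
#' @param value nonnegative number.
#' @param unit one of `"years"`, `"months"`, `"weeks"`, `"days"`.
#' @return the age in years.
#' @examples
#' convertAge(12, "months")  # 1
#' convertAge(365.25, "days")  # 1
#' @export
convertAge <- function(value, unit) {
  factors <- c(years = 1, months = 1 / 12, weeks = 7 / 365.25,
               days = 1 / 365.25)
  if (length(unit) != 1 || !unit %in% names(factors))
    glStop(paste0("cannot convert age with unit '", unit,
                  "'; resolve defaults first"), "geolabel_unit_error")
  value * factors[[unit]]
}

#' Extract a sex label from sample metadata text
#'
#' Searches the metadata fields in order and stops at the first field class
#' that yields a match. Within Characteristics, pairs whose key matches
#' `sex`/`gender` are inspected first and their value is looked up in the
#' vocabulary (`male`/`m`/`man`, `female`/`f`/`woman`, case-insensitive
#' whole tokens); the numeric coding `1` = male / `0` = female is accepted
#' only under such an explicit key and carries confidence 0.5. In free-text
#' fields only explicit `sex: M` / `gender = female` style patterns fire.
#' Contradictory matches within one field class (both sexes seen) yield no
#' label and a warning.
#'
#' @param meta a [SampleMetadata-class] object.
#' @param order a [fieldOrder()] object.
#' @param patterns pattern table, see [defaultPatternTable()].
#' @param aggressive also match implicit parenthetical forms such as
#'   `"(34, F, non-smoker)"`. Off by default (precision-first).
#' @return a [SampleLabel-class] `SexLabel`, or `NULL` when no field yields
#'   an unambiguous match.
#' @export
extractSex <- function(meta, order = fieldOrder(),
                       patterns = defaultPatternTable(),
                       aggressive = FALSE) {
  vocab <- sexVocabulary(patterns)
  lexical <- vocab[!vocab$keyed_only, , drop = FALSE]
  keyRe <- "(sex|gender)"
  tokenRe <- paste0("\\b(?:sex|gender)\\s*[:=]\\s*([A-Za-z01]+)\\b")
  lookup <- function(token, keyed) {
    token <- tolower(token)
    tab <- if (keyed) vocab else lexical
    i <- match(token, tab$pattern)
    if (is.na(i)) NULL else tab[i, , drop = FALSE]
  }
  for (fieldClass in order) {
    entries <- fieldTexts(meta, fieldClass, keyPattern = keyRe)
    found <- list()
    for (e in entries) {
      keyed <- !is.na(e$key) && grepl(keyRe, e$key, ignore.case = TRUE)
      if (keyed) {
        hit <- lookup(trimws(e$value), keyed = TRUE)
        if (!is.null(hit))
          found[[length(found) + 1L]] <-
            list(value = hit$value, conf = hit$confidence,
                 field = e$field, text = paste0(e$key, ": ", e$value))
        next
      }
      text <- if (!is.na(e$key)) paste0(e$key, ": ", e$value) else e$value
      m <- regmatches(text, gregexpr(tokenRe, text, ignore.case = TRUE,
                                     perl = TRUE))[[1]]
      for (frag in m) {
        token <- sub(".*[:=]\\s*", "", frag)
        hit <- lookup(token, keyed = TRUE)  # explicit key present in text
        if (!is.null(hit))
          found[[length(found) + 1L]] <-
            list(value = hit$value, conf = hit$confidence,
                 field = e$field, text = frag)
      }
      if (aggressive) {
        am <- regmatches(text,
          regexpr("\\(\\s*[0-9]{1,3}\\s*,\\s*([MFmf])\\s*,", text,
                  perl = TRUE))
        if (length(am) && nzchar(am)) {
          token <- toupper(gsub("[^MFmf]", "", am))
          found[[length(found) + 1L]] <-
            list(value = if (token == "M") "male" else "female",
                 conf = 0.5, field = e$field, text = am)
        }
      }
    }
    if (length(found)) {
      values <- unique(vapply(found, `[[`, "", "value"))
      if (length(values) > 1) {
        warning("contradictory sex annotations in field class '", fieldClass,
                "' of ", meta@sampleId, "; no label assigned")
        return(NULL)
      }
      f <- found[[1]]
      return(new("SexLabel", sampleId = meta@sampleId, value = f$value,
                 source = "text", matchedField = f$field,
                 matchedText = f$text, confidence = f$conf))
    }
  }
  NULL
}

## Parse "<number> <unit?>" out of a value string; returns NULL or
## list(value, unitToken). Leading +/- rejected (negative ages never match).
parseAgeValue <- function(text) {
  m <- regexpr("^\\s*([0-9]+(?:\\.[0-9]+)?)\\s*\\(?([A-Za-z]+)?", text,
               perl = TRUE)
  if (m < 0) return(NULL)
  st <- attr(m, "capture.start"); len <- attr(m, "capture.length")
  num <- substr(text, st[1], st[1] + len[1] - 1L)
  unit <- if (len[2] > 0) substr(text, st[2], st[2] + len[2] - 1L) else ""
  list(value = as.numeric(num), unitToken = tolower(unit))
}

## Unit named inside a key like "age (mo)", "age in weeks", "age_yrs"
parseKeyUnit <- function(key) {
  m <- regexpr("age[^A-Za-z]*\\(?\\s*(?:in\\s+)?([A-Za-z]+)", key,
               ignore.case = TRUE, perl = TRUE)
  if (m < 0) return("")
  st <- attr(m, "capture.start"); len <- attr(m, "capture.length")
  tolower(substr(key, st[1], st[1] + len[1] - 1L))
}

#' Extract an age label from sample metadata text
#'
#' Recognizes key-value forms `age: 29 y`, unit-in-key forms
#' `age (mo): 520`, and bare `age: 47`. The unit is taken from the value
#' text when present, else from the key, else the species default applies
#' (years for human, months for rodents, decided on the organism field) and
#' the label is flagged `unitWasDefault`. An unrecognized unit token (e.g.
#' a misspelling) is treated as absent, so the default applies — the failure
#' mode that makes downstream plausibility bounding necessary. The canonical
#' value in years must fall inside `cfg$plausibleRangeYears`, otherwise the
#' match is discarded with a warning and the search continues.
#'
#' @inheritParams extractSex
#' @param cfg an [ageConfig()] object.
#' @return an `AgeLabel` (see [SampleLabel-class]) or `NULL`.
#' @export
extractAge <- function(meta, order = fieldOrder(), cfg = ageConfig()) {
  defUnit <- speciesDefaultUnit(meta@organism, cfg)
  syn <- cfg$unitSynonymTable
  keyRe <- "(^|[^[:alpha:]])age([^[:alpha:]]|$)"
  freeRe <- paste0("\\bage\\s*(?:\\(\\s*(?:in\\s+)?([A-Za-z]+)\\.?\\s*\\))?",
                   "\\s*[:=]\\s*([0-9]+(?:\\.[0-9]+)?)\\s*([A-Za-z]+)?")
  makeLabel <- function(value, unitToken, keyUnitToken, field, text) {
    rawUnit <- "unknown"; wasDefault <- FALSE
    if (nzchar(unitToken) && unitToken %in% names(syn)) {
      rawUnit <- syn[[unitToken]]
    } else if (nzchar(keyUnitToken) && keyUnitToken %in% names(syn)) {
      rawUnit <- syn[[keyUnitToken]]
    }
    unit <- rawUnit
    if (unit == "unknown") { unit <- defUnit; wasDefault <- TRUE }
    years <- convertAge(value, unit)
    rng <- cfg$plausibleRangeYears
    if (years < rng[1] || years > rng[2]) {
      warning("age ", value, " ", unit, " (", signif(years, 4),
              " years) in ", meta@sampleId,
              " outside plausible range; discarded")
      return(NULL)
    }
    new("AgeLabel", sampleId = meta@sampleId, rawValue = value,
        rawUnit = rawUnit, valueYears = years, unitWasDefault = wasDefault,
        source = "text", matchedField = field, matchedText = text,
        confidence = 1)
  }
  for (fieldClass in order) {
    entries <- fieldTexts(meta, fieldClass, keyPattern = keyRe)
    for (e in entries) {
      keyed <- !is.na(e$key) && grepl(keyRe, e$key, ignore.case = TRUE)
      if (keyed) {
        parsed <- parseAgeValue(e$value)
        if (is.null(parsed)) next
        lab <- makeLabel(parsed$value, parsed$unitToken,
                         parseKeyUnit(e$key), e$field,
                         paste0(e$key, ": ", e$value))
        if (!is.null(lab)) return(lab)
        next
      }
      text <- if (!is.na(e$key)) paste0(e$key, ": ", e$value) else e$value
      m <- regexpr(freeRe, text, ignore.case = TRUE, perl = TRUE)
      if (m < 0) next
      st <- attr(m, "capture.start"); len <- attr(m, "capture.length")
      cap <- function(i) if (len[i] > 0)
        substr(text, st[i], st[i] + len[i] - 1L) else ""
      lab <- makeLabel(as.numeric(cap(2)), tolower(cap(3)),
                       tolower(cap(1)), e$field,
                       substr(text, m, m + attr(m, "match.length") - 1L))
      if (!is.null(lab)) return(lab)
    }
  }
  NULL
}
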
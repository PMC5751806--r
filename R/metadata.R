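#' Parse a GEO Characteristics field into ordered key-value pairs
#'
#' GEO samples carry investigator-supplied "Characteristics" annotations as a
#' single free-text cell per channel, holding pairs such as `Age: 25 days;
#' Tissue: Pancreas`. This splits the cell into pairs and each pair on its
#' *first* colon, so values may themselves contain colons. Segments with no
#' colon become a pair with an empty key. The function is total: any string
#' (including `""` and `NA`) yields a well-formed, possibly empty, table.
#'
#' @param raw a single character string (the raw cell).
#' @param separators character vector of pair separators; the defaults are
#'   semicolon, tab and newline. GEOmetadb does not document its delimiter,
#'   so this is configurable.
#' @return a data frame with character columns `key` and `value`, one row per
#'   pair, in order of appearance; keys and values are whitespace-trimmed.
#' @examples
#' parseCharacteristics("Age: 25 days; Tissue: Pancreas")
#' parseCharacteristics("tissue: liver: left lobe")  # splits on first colon
#' @export
parseCharacteristics <- function(raw, separators = c(";", "\t", "\n")) {
  empty <- data.frame(key = character(), value = character(),
                      stringsAsFactors = FALSE)
  if (length(raw) == 0 || is.na(raw) || !nzchar(trimws(raw))) return(empty)
  sepRe <- paste0("[", paste(vapply(separators, function(s)
    gsub("([][\\^$.|?*+()-])", "\\\\\\1", s), ""), collapse = ""), "]")
  segs <- trimws(strsplit(raw, sepRe)[[1]])
  segs <- segs[nzchar(segs)]
  if (!length(segs)) return(empty)
  keys <- character(length(segs)); vals <- character(length(segs))
  for (i in seq_along(segs)) {
    pos <- regexpr(":", segs[i], fixed = TRUE)
    if (pos > 0) {
      keys[i] <- trimws(substr(segs[i], 1L, pos - 1L))
      vals[i] <- trimws(substr(segs[i], pos + 1L, nchar(segs[i])))
    } else {
      keys[i] <- ""
      vals[i] <- segs[i]
    }
  }
  data.frame(key = keys, value = vals, stringsAsFactors = FALSE)
}

#' Serialize key-value pairs back to a Characteristics string
#'
#' Inverse of [parseCharacteristics()] for colon-free keys: the round trip
#' `parseCharacteristics(serializeCharacteristics(df))` returns `df`.
#'
#' @param pairs data frame with columns `key`, `value`.
#' @param sep pair separator, default `"; "`.
#' @return a single string.
#' @export
serializeCharacteristics <- function(pairs, sep = "; ") {
  if (!nrow(pairs)) return("")
  paste(ifelse(nzchar(pairs$key),
               paste0(pairs$key, ": ", pairs$value),
               pairs$value),
        collapse = sep)
}

#' Construct a SampleMetadata record
#'
#' @param sampleId GEO sample accession; mandatory, nonempty.
#' @param seriesId,platformId,organism,molecule,title,description free-text
#'   fields, defaulting to `""`. `NA` is normalized to `""`.
#' @param sourceName named character vector of per-channel source names
#'   (names are channel numbers); an unnamed scalar is taken as channel 1.
#' @param characteristics named character vector of per-channel raw
#'   characteristics strings; parsed eagerly via [parseCharacteristics()].
#' @param extraFields named character vector of any further columns.
#' @return a [SampleMetadata-class] object.
#' @examples
#' m <- sampleMetadata("GSM1", title = "liver biopsy",
#'                     characteristics = c(`1` = "Sex: F; Age: 61 years"))
#' characteristics(m)
#' @export
sampleMetadata <- function(sampleId, seriesId = "", platformId = "",
                           organism = "", molecule = "", title = "",
                           description = "", sourceName = character(),
                           characteristics = character(),
                           extraFields = character()) {
  chr1 <- function(x) {
    x <- as.character(x)
    if (!length(x)) return("")
    if (is.na(x[1])) "" else x[1]
  }
  channelize <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    if (length(x) && is.null(names(x))) names(x) <- as.character(seq_along(x))
    x
  }
  rawCh <- channelize(characteristics)
  new("SampleMetadata",
      sampleId = chr1(sampleId), seriesId = chr1(seriesId),
      platformId = chr1(platformId), organism = chr1(organism),
      molecule = chr1(molecule), title = chr1(title),
      description = chr1(description),
      sourceName = channelize(sourceName),
      characteristicsRaw = rawCh,
      characteristics = lapply(rawCh, parseCharacteristics),
      extraFields = {
        e <- as.character(extraFields); names(e) <- names(extraFields)
        e[is.na(e)] <- ""; e
      })
}

#' @describeIn sampleMetadata accession of the sample
#' @param x,object a `SampleMetadata` object
#' @export
sampleId <- function(x) x@sampleId

#' @describeIn sampleMetadata series (experiment) accession
#' @export
seriesId <- function(x) x@seriesId

#' @describeIn sampleMetadata parsed characteristics: named list (by channel)
#'   of key-value data frames
#' @export
characteristics <- function(x) x@characteristics

#' @describeIn sampleMetadata species string
#' @export
organism <- function(x) x@organism

setMethod("show", "SampleMetadata", function(object) {
  cat("SampleMetadata", object@sampleId,
      if (nzchar(object@seriesId)) paste0("(", object@seriesId, ")"), "\n")
  if (nzchar(object@title)) cat("  title: ", object@title, "\n", sep = "")
  for (ch in names(object@characteristics)) {
    p <- object@characteristics[[ch]]
    if (nrow(p))
      cat(sprintf("  characteristics ch%s: %s\n", ch,
                  paste(p$key, p$value, sep = "=", collapse = "; ")))
  }
  invisible(object)
})

#' Canonical metadata field search order
#'
#' The extractors search a sample's fields in a fixed order and stop at the
#' first field class that yields a label: the parsed Characteristics pairs
#' first (the experimenter has explicitly named those attributes), then
#' Description, Source Name, Title, and finally any extra fields.
#'
#' @param fields character vector of field-class names; the default is the
#'   canonical order.
#' @return a character vector with class `"FieldOrder"`.
#' @export
fieldOrder <- function(fields = c("characteristics", "description",
                                  "source_name", "title", "extra")) {
  known <- c("characteristics", "description", "source_name", "title", "extra")
  bad <- setdiff(fields, known)
  if (length(bad))
    stop("unknown field classes: ", paste(bad, collapse = ", "))
  structure(fields, class = "FieldOrder")
}

## Ordered candidate texts for one field class of one sample. Each entry is
## list(field, key, value): for characteristics entries `key` is the pair
## key (pairs whose key matches keyPattern come first; channel 1 before 2);
## for the free-text fields `key` is NA and `value` the whole field.
fieldTexts <- function(meta, fieldClass, keyPattern = NULL) {
  out <- list()
  add <- function(field, value, key = NA_character_) {
    if (nzchar(value))
      out[[length(out) + 1L]] <<- list(field = field, key = key, value = value)
  }
  switch(fieldClass,
    characteristics = {
      chans <- names(meta@characteristics)
      chans <- chans[order(suppressWarnings(as.integer(chans)))]
      for (ch in chans) {
        p <- meta@characteristics[[ch]]
        if (!nrow(p)) next
        fname <- paste0("characteristics_ch", ch)
        hit <- if (!is.null(keyPattern))
          grepl(keyPattern, p$key, ignore.case = TRUE) else
          rep(FALSE, nrow(p))
        for (i in c(which(hit), which(!hit)))
          add(fname, p$value[i], key = p$key[i])
      }
    },
    description = add("description", meta@description),
    source_name = {
      chans <- names(meta@sourceName)
      chans <- chans[order(suppressWarnings(as.integer(chans)))]
      for (ch in chans) add(paste0("source_name_ch", ch), meta@sourceName[[ch]])
    },
    title = add("title", meta@title),
    extra = {
      for (nm in names(meta@extraFields)) add(nm, meta@extraFields[[nm]])
    })
  out
}
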
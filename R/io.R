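## Structured errors: all fatal geolabel conditions carry class
## "geolabel_error" plus a specific subclass, so callers can test for them.
glStop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "geolabel_error")))
}

## Column aliases: GEOmetadb dialect on the left, canonical on the right.
## Channelled fields are matched by regex so any chN is picked up.
.columnAliases <- c(
  gsm = "sample_id", geo_accession = "sample_id", sample_id = "sample_id",
  series_id = "series_id", gse = "series_id",
  gpl = "platform_id", platform_id = "platform_id",
  title = "title", description = "description",
  source_name = "source_name_ch1", characteristics = "characteristics_ch1",
  organism = "organism_ch1", molecule = "molecule_ch1"
)

## Turn one row (named character vector / 1-row data.frame) into SampleMetadata
metadataFromRow <- function(row, aliases = .columnAliases) {
  row <- unlist(row)
  row[is.na(row)] <- ""
  nm <- names(row)
  canon <- ifelse(nm %in% names(aliases), aliases[nm], nm)
  pick <- function(col) {
    i <- which(canon == col)
    if (length(i)) row[[i[1]]] else ""
  }
  channelled <- function(stem) {
    i <- grep(paste0("^", stem, "_ch([0-9]+)$"), canon)
    v <- as.character(row[i])
    names(v) <- sub(paste0("^", stem, "_ch"), "", canon[i])
    v[order(as.integer(names(v)))]
  }
  sid <- pick("sample_id")
  if (!nzchar(sid))
    glStop("metadata row lacks a sample id (gsm/sample_id column)",
           "geolabel_missing_id")
  used <- canon %in% c("sample_id", "series_id", "platform_id", "title",
                       "description") |
    grepl("^(source_name|characteristics|organism|molecule)_ch[0-9]+$", canon)
  extra <- as.character(row[!used])
  names(extra) <- nm[!used]
  org <- channelled("organism"); mol <- channelled("molecule")
  sampleMetadata(
    sampleId = sid, seriesId = pick("series_id"),
    platformId = pick("platform_id"),
    organism = if (length(org)) org[[1]] else "",
    molecule = if (length(mol)) mol[[1]] else "",
    title = pick("title"), description = pick("description"),
    sourceName = channelled("source_name"),
    characteristics = channelled("characteristics"),
    extraFields = extra[nzchar(extra)])
}

#' Read GEO sample metadata from a GEOmetadb-style SQLite database
#'
#' Reads one [SampleMetadata-class] record per row of a sample table.
#' GEOmetadb column names (`gsm`, `gpl`, `characteristics_ch1`, ...) and
#' generic names (`sample_id`, `characteristics`, ...) are both accepted;
#' columns that map to no known field are kept in `extraFields`.
#' Characteristics cells are parsed eagerly.
#'
#' @param path path to the SQLite file.
#' @param table table name to read, default `"gsm"`.
#' @param query optional full SQL query overriding `table`.
#' @return a list of [SampleMetadata-class] objects.
#' @export
readMetadataSQLite <- function(path, table = "gsm", query = NULL) {
  if (!file.exists(path))
    glStop(paste0("SQLite file not found: ", path), "geolabel_io_error")
  con <- tryCatch(DBI::dbConnect(RSQLite::SQLite(), path),
                  error = function(e)
                    glStop(paste0("cannot open SQLite file: ",
                                  conditionMessage(e)), "geolabel_io_error"))
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  sql <- if (is.null(query)) paste0("SELECT * FROM ", table) else query
  df <- tryCatch(DBI::dbGetQuery(con, sql),
                 error = function(e)
                   glStop(paste0("SQLite query failed: ",
                                 conditionMessage(e)), "geolabel_io_error"))
  lapply(seq_len(nrow(df)), function(i) metadataFromRow(df[i, , drop = FALSE]))
}

#' Read GEO sample metadata from TSV or JSON-lines
#'
#' The two flat formats carry the same fields as the SQLite table (same
#' column-name dialects). The format is inferred from the extension
#' (`.json`/`.jsonl` vs anything else = TSV) unless given.
#'
#' @param path input file.
#' @param format `"auto"`, `"tsv"` or `"jsonl"`.
#' @return a list of [SampleMetadata-class] objects.
#' @export
readMetadataTabular <- function(path, format = c("auto", "tsv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path))
    glStop(paste0("metadata file not found: ", path), "geolabel_io_error")
  if (format == "auto")
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE))
      "jsonl" else "tsv"
  if (format == "tsv") {
    df <- utils::read.delim(path, colClasses = "character",
                            check.names = FALSE, na.strings = NULL)
    lapply(seq_len(nrow(df)),
           function(i) metadataFromRow(df[i, , drop = FALSE]))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    lapply(lines, function(l) {
      rec <- jsonlite::fromJSON(l)
      metadataFromRow(rapply(rec, as.character, how = "unlist"))
    })
  }
}

#' Write sample metadata to TSV
#'
#' Counterpart of [readMetadataTabular()], using the GEOmetadb column
#' dialect; extra fields become additional columns.
#'
#' @param metas list of [SampleMetadata-class] objects.
#' @param path output file.
#' @export
writeMetadataTabular <- function(metas, path) {
  rows <- lapply(metas, function(m) {
    base <- c(gsm = m@sampleId, series_id = m@seriesId, gpl = m@platformId,
              title = m@title, description = m@description)
    ch <- m@characteristicsRaw
    if (length(ch)) names(ch) <- paste0("characteristics_ch", names(ch))
    sn <- m@sourceName
    if (length(sn)) names(sn) <- paste0("source_name_ch", names(sn))
    org <- if (nzchar(m@organism)) c(organism_ch1 = m@organism) else character()
    mol <- if (nzchar(m@molecule)) c(molecule_ch1 = m@molecule) else character()
    c(base, ch, sn, org, mol, m@extraFields)
  })
  cols <- unique(unlist(lapply(rows, names)))
  df <- as.data.frame(do.call(rbind, lapply(rows, function(r) {
    out <- stats::setNames(rep("", length(cols)), cols)
    out[names(r)] <- r
    out
  })), stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert extracted labels to a flat table
#'
#' @param labels a list of [SampleLabel-class] objects (`NULL` elements, the
#'   extractors' "no label", are dropped).
#' @return data frame with columns `sample_id`, `label_type`, `value`,
#'   `unit`, `source`, `confidence`, `matched_field`, `matched_text`. For
#'   age labels `value` is the canonical age in years and `unit` the raw
#'   unit as written (or `"default:<unit>"` when the species default was
#'   applied); for tissue labels `value` is the ontology term id.
#' @export
labelsToFrame <- function(labels) {
  labels <- Filter(Negate(is.null), labels)
  rows <- lapply(labels, function(l) {
    tv <- if (is(l, "SexLabel")) c("sex", l@value, "")
    else if (is(l, "AgeLabel"))
      c("age", format(l@valueYears, digits = 12),
        if (l@unitWasDefault) paste0("default:", l@rawUnit) else l@rawUnit)
    else if (is(l, "TissueLabel")) c("tissue", l@termId, "")
    else stop("unknown label class: ", class(l))
    data.frame(sample_id = l@sampleId, label_type = tv[1], value = tv[2],
               unit = tv[3], source = l@source,
               confidence = l@confidence, matched_field = l@matchedField,
               matched_text = l@matchedText, stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(sample_id = character(), label_type = character(),
                      value = character(), unit = character(),
                      source = character(), confidence = numeric(),
                      matched_field = character(), matched_text = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write / read extracted labels as TSV
#'
#' The on-disk label format is a plain TSV with the [labelsToFrame()]
#' columns; `readLabels` returns that data frame unchanged, so a write/read
#' round trip is the identity.
#'
#' @param labels list of [SampleLabel-class] objects or a data frame already
#'   in [labelsToFrame()] layout.
#' @param path file path.
#' @return `readLabels`: the label data frame.
#' @export
writeLabels <- function(labels, path) {
  df <- if (is.data.frame(labels)) labels else labelsToFrame(labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeLabels
#' @export
readLabels <- function(path) {
  if (!file.exists(path))
    glStop(paste0("label file not found: ", path), "geolabel_io_error")
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, na.strings = NULL)
  df$confidence <- as.numeric(df$confidence)
  df
}
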
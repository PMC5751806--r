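test_that("characteristics parsing splits pairs and first colons", {
  p <- parseCharacteristics(paste(
    "Genetic Background: NOD",
    "Transgene: BDC2.5 T cell receptor genes",
    "Age: 25 days", "Tissue: Pancreas",
    "Isolation: FACS on CD45+ Hoechst- (viable) cells", sep = "; "))
  expect_equal(nrow(p), 5)
  expect_equal(unlist(p[3, ]), c(key = "Age", value = "25 days"))
  expect_equal(unlist(p[4, ]), c(key = "Tissue", value = "Pancreas"))

  expect_equal(nrow(parseCharacteristics("")), 0)
  expect_equal(nrow(parseCharacteristics(NA_character_)), 0)

  ## first-colon rule: values may contain colons
  p2 <- parseCharacteristics("tissue: liver: left lobe")
  expect_equal(p2$key, "tissue")
  expect_equal(p2$value, "liver: left lobe")

  ## tab and newline delimiters, no-colon segment -> empty key
  p3 <- parseCharacteristics("a: 1\tb: 2\nplain text")
  expect_equal(p3$key, c("a", "b", ""))
  expect_equal(p3$value, c("1", "2", "plain text"))
})

test_that("parse/serialize round trip holds for colon-free keys", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(1:5, 1)
    pairs <- data.frame(
      key = replicate(n, paste(sample(letters, 5), collapse = "")),
      value = replicate(n, paste(sample(c(letters, " ", "+", "-"), 8,
                                        replace = TRUE), collapse = "")),
      stringsAsFactors = FALSE)
    pairs$value <- trimws(pairs$value)
    pairs <- pairs[nzchar(pairs$value), , drop = FALSE]
    rownames(pairs) <- NULL
    expect_identical(parseCharacteristics(serializeCharacteristics(pairs)),
                     pairs)
  }
})

test_that("SampleMetadata validity enforces id and characteristics sync", {
  expect_error(sampleMetadata(""), "sampleId")
  m <- fixturePancreasSample()
  expect_s4_class(m, "SampleMetadata")
  expect_true(validObject(m))
  ## tampering with the parsed slot breaks validity
  bad <- m
  bad@characteristics[["1"]]$value[1] <- "tampered"
  expect_error(validObject(bad), "parse")
})

test_that("field order defaults to characteristics first", {
  fo <- fieldOrder()
  expect_equal(fo[1], "characteristics",
               ignore_attr = TRUE)
  expect_equal(as.character(fo),
               c("characteristics", "description", "source_name", "title",
                 "extra"))
  expect_error(fieldOrder(c("characteristics", "bogus")), "unknown field")
})

test_that("SQLite reader maps GEOmetadb columns and handles NULLs", {
  db <- tempfile(fileext = ".sqlite")
  con <- DBI::dbConnect(RSQLite::SQLite(), db)
  DBI::dbWriteTable(con, "gsm", data.frame(
    gsm = c("GSM1", "GSM2", "GSM3"),
    series_id = "GSE9", gpl = "GPL96",
    title = c("t1", "t2", "t3"),
    description = c("d1", NA, "d3"),
    source_name_ch1 = "liver",
    characteristics_ch1 = c("Sex: F; Age: 61 years", "", "Sex: M"),
    characteristics_ch2 = c("strain: B6", NA, NA),
    organism_ch1 = "Homo sapiens",
    molecule_ch1 = "total RNA",
    custom_note = c("x", "y", "z"),
    stringsAsFactors = FALSE))
  DBI::dbDisconnect(con)

  metas <- readMetadataSQLite(db)
  expect_length(metas, 3)
  expect_equal(vapply(metas, sampleId, ""), c("GSM1", "GSM2", "GSM3"))
  expect_equal(metas[[2]]@description, "")            # NULL -> empty
  expect_equal(names(characteristics(metas[[1]])), c("1", "2"))
  expect_equal(characteristics(metas[[1]])[["2"]]$value, "B6")
  expect_equal(unname(metas[[1]]@extraFields["custom_note"]), "x")

  expect_error(readMetadataSQLite(tempfile()), "not found",
               class = "geolabel_error")
  ## table without an id column is a named fatal error
  con <- DBI::dbConnect(RSQLite::SQLite(), db)
  DBI::dbWriteTable(con, "noid", data.frame(title = "x"))
  DBI::dbDisconnect(con)
  expect_error(readMetadataSQLite(db, table = "noid"),
               class = "geolabel_missing_id")
})

test_that("TSV and JSON-lines readers agree and keep unknown columns", {
  df <- data.frame(sample_id = c("GSM10", "GSM11"),
                   series_id = "GSE5", title = c("a", "b"),
                   characteristics = c("Sex: female", ""),
                   mystery = c("u", "v"), stringsAsFactors = FALSE)
  tsv <- tempfile(fileext = ".tsv")
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jl <- tempfile(fileext = ".jsonl")
  writeLines(vapply(seq_len(nrow(df)), function(i)
    jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE), ""), jl)

  a <- readMetadataTabular(tsv)
  b <- readMetadataTabular(jl)
  expect_equal(a, b)
  expect_equal(vapply(a, sampleId, ""), df$sample_id)
  expect_equal(unname(a[[1]]@extraFields["mystery"]), "u")
  expect_equal(characteristics(a[[1]])[["1"]]$value, "female")
  ## metadata without characteristics -> empty characteristics
  tsv2 <- tempfile(fileext = ".tsv")
  write.table(df[, c("sample_id", "title")], tsv2, sep = "\t",
              quote = FALSE, row.names = FALSE)
  c_ <- readMetadataTabular(tsv2)
  expect_length(characteristics(c_[[1]]), 0)
})

test_that("metadata and label writers round-trip", {
  g <- fixtureOntology()
  corpus <- genMetadata(corpusSpec(nSamples = 15, nSeries = 3,
                                   labelPresence = c(sex = 1, age = 1,
                                                     tissue = 1),
                                   seed = 2), g)
  tsv <- tempfile(fileext = ".tsv")
  writeMetadataTabular(corpus$metadata, tsv)
  back <- readMetadataTabular(tsv)
  expect_equal(vapply(back, sampleId, ""),
               vapply(corpus$metadata, sampleId, ""))
  expect_equal(lapply(back, characteristics),
               lapply(corpus$metadata, characteristics))

  res <- extractAll(corpus$metadata, c("sex", "age"), graph = NULL)
  lf <- labelsToFrame(res$labels)
  out <- tempfile(fileext = ".tsv")
  writeLabels(res$labels, out)
  expect_equal(readLabels(out), lf)
})
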
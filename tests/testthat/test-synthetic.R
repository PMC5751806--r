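test_that("generators are bit-reproducible under a seed", {
  g1 <- genToyOntology(nTerms = 20, seed = 5)
  g2 <- genToyOntology(nTerms = 20, seed = 5)
  expect_equal(termNames(g1), termNames(g2))
  expect_equal(g1@parents, g2@parents)

  spec <- corpusSpec(nSamples = 40, nSeries = 8, seed = 6)
  c1 <- genMetadata(spec, g1); c2 <- genMetadata(spec, g1)
  expect_equal(c1$truth, c2$truth)
  expect_equal(c1$metadata, c2$metadata)

  es <- expressionSpec(nGenes = 300, nInformative = 5, seed = 7)
  ## few genes: restrict to corpora whose tissues fit the blocks
  e1 <- genExpression(es, c1$truth)
  e2 <- genExpression(es, c2$truth)
  expect_equal(exprsValues(e1), exprsValues(e2))
})

test_that("toy ontology round-trips through OBO and matches its own depths", {
  g <- genToyOntology(nTerms = 25, nSynonyms = 2, seed = 9)
  path <- tempfile(fileext = ".obo")
  writeOBO(g, path)
  back <- loadOBO(path)
  expect_equal(termIds(back), termIds(g))
  expect_equal(termNames(back), termNames(g))
  expect_equal(back@parents, g@parents)
  expect_equal(lapply(back@synonyms, `[[`, "text"),
               lapply(g@synonyms, `[[`, "text"))
  ## generator's incremental depths == package BFS depths
  expect_equal(attr(g, "generatorDepths"),
               setNames(termDepth(g, termIds(g)), termIds(g)))
  ## degenerate single-term graph
  g1 <- genToyOntology(nTerms = 1, seed = 1)
  expect_equal(termDepth(g1, termIds(g1)), 0)
  expect_equal(unique(randomDistanceBaseline(g1, 20, seed = 1)), 0)
})

test_that("full presence with explicit templates closes the loop exactly", {
  g <- fixtureOntology()
  spec <- corpusSpec(
    nSamples = 60, nSeries = 6,
    labelPresence = c(sex = 1, age = 1, tissue = 1),
    phrasingWeights = list(
      sex = c(explicit = 1, abbreviated = 0, numeric = 0, implicit = 0),
      age = c(keyvalue_unit = 1, unit_in_key = 0, bare = 0,
              misspelled_unit = 0, implicit = 0),
      tissue = c(characteristics = 1, source_name = 0, freetext = 0,
                 derived_adjective = 0)),
    seed = 11)
  corpus <- genMetadata(spec, g)
  res <- extractAll(corpus$metadata, graph = g)
  expect_equal(unname(res$coverage), c(1, 1, 1))
  labs <- labelsToFrame(res$labels)
  tr <- corpus$truth
  ## recall and precision 1.0: every sample labeled, every label correct
  sx <- labs[labs$label_type == "sex", ]
  expect_equal(nrow(sx), nrow(tr))
  expect_equal(sx$value, tr$sex[match(sx$sample_id, tr$sample_id)])
  ts <- labs[labs$label_type == "tissue", ]
  expect_equal(ts$value, tr$tissue_id[match(ts$sample_id, tr$sample_id)])
  ag <- labs[labs$label_type == "age", ]
  expect_equal(as.numeric(ag$value),
               tr$age_expected_years[match(ag$sample_id, tr$sample_id)],
               tolerance = 1e-9)
  ## and the encodings stay within half a unit of the true age
  expect_true(all(abs(as.numeric(ag$value) -
                        tr$age_years[match(ag$sample_id, tr$sample_id)])
                  <= 0.05 + 1e-9))
})

test_that("extractor hits match the generator's expectation flags exactly", {
  g <- fixtureOntology()
  corpus <- genMetadata(corpusSpec(nSamples = 250, nSeries = 20, seed = 17),
                        g)
  res <- extractAll(corpus$metadata, graph = g)
  tr <- corpus$truth
  log <- res$log
  for (lt in c("sex", "age", "tissue")) {
    hit <- log$status[log$label_type == lt] == "hit"
    expect_equal(hit, tr[[paste0(lt, "_expected")]],
                 info = lt)
  }
  ## planted-pattern precision: every emitted sex label is correct
  labs <- labelsToFrame(res$labels)
  sx <- labs[labs$label_type == "sex", ]
  expect_equal(sx$value, tr$sex[match(sx$sample_id, tr$sample_id)])
  ## adversarial templates never fire
  implicitIds <- tr$sample_id[!is.na(tr$sex_template) &
                                tr$sex_template == "implicit"]
  expect_false(any(sx$sample_id %in% implicitIds))
  adjIds <- tr$sample_id[!is.na(tr$tissue_template) &
                           tr$tissue_template == "derived_adjective"]
  ts <- labs[labs$label_type == "tissue", ]
  expect_false(any(ts$sample_id %in% adjIds))
})

test_that("null and strong expression effects bracket classifier skill", {
  g <- fixtureOntology()
  tr <- genMetadata(corpusSpec(nSamples = 160, nSeries = 16, seed = 19),
                    g)$truth
  y <- setNames(tr$sex, tr$sample_id)
  folds <- makeFolds(tr$series_id, k = 8, seed = 19)
  ## effect 0: accuracy near the majority rate of the series-biased corpus
  se0 <- genExpression(expressionSpec(nGenes = 400, nInformative = 10,
                                      effectSize = 0, seriesSd = 0,
                                      seed = 20), tr)
  cv0 <- crossValidate(se0, y, "sex", mlConfig(seed = 20), folds = folds)
  expect_lt(cv0$metrics$accuracy, 0.7)
  ## strong effect: near-perfect recovery
  se3 <- genExpression(expressionSpec(nGenes = 400, nInformative = 10,
                                      effectSize = 3, seriesSd = 0.5,
                                      seed = 20), tr)
  cv3 <- crossValidate(se3, y, "sex", mlConfig(seed = 20), folds = folds)
  expect_gt(cv3$metrics$macro["precision"], 0.95)
  expect_gt(cv3$metrics$macro["recall"], 0.95)
  ## the selected panel recovers the planted informative genes
  info <- S4Vectors::metadata(se3)$informativeGenes$sex
  sel <- selectFeatures(se3, y, mlConfig(nFeatures = 100))
  expect_gte(mean(info %in% sel), 0.5)
})

test_that("missing-value planting stays below half and is imputable", {
  g <- fixtureOntology()
  tr <- genMetadata(corpusSpec(nSamples = 30, nSeries = 6, seed = 23),
                    g)$truth
  se <- genExpression(expressionSpec(nGenes = 200, nInformative = 5,
                                     missingRate = 0.05, seed = 23), tr)
  v <- exprsValues(se)
  expect_gt(sum(is.na(v)), 0)
  expect_equal(mean(is.na(v)), 0.05, tolerance = 0.01)
  imp <- knnImpute(se)
  expect_false(anyNA(exprsValues(imp)))
})
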
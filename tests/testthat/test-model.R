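test_that("ANOVA F scores match the closed form and rank informative genes", {
  ## printed 2x3 toy: class A = (1, 2, 3), class B = (4, 6, 8)
  x <- c(1, 2, 3); y <- c(4, 6, 8)
  v <- matrix(c(x, y), 1, 6, dimnames = list("g1", paste0("s", 1:6)))
  groups <- rep(c("A", "B"), each = 3)
  fMine <- geolabel:::rowFStatistic(v, groups)
  ## hand-computed: means 2 and 6, grand 4, SSB = 3*4 + 3*4 = 24 (df 1),
  ## SSW = 2 + 8 = 10 (df 4) -> F = 24 / 2.5 = 9.6
  expect_equal(unname(fMine), 9.6)
  ## equals anova()'s F and the squared pooled t
  aovF <- anova(lm(c(x, y) ~ groups))[["F value"]][1]
  expect_equal(unname(fMine), aovF)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(unname(fMine), unname(tt$statistic^2))

  ## three-class case against anova() per gene
  withSeed(8, {
    v3 <- matrix(rnorm(90), 6, 15)
    rownames(v3) <- paste0("g", 1:6)
    g3 <- rep(c("A", "B", "C"), each = 5)
    f3 <- geolabel:::rowFStatistic(v3, g3)
    for (i in 1:6)
      expect_equal(unname(f3[i]),
                   anova(lm(v3[i, ] ~ g3))[["F value"]][1])
  })
})

test_that("feature selection filters variance then takes top F", {
  withSeed(21, {
    v <- matrix(rnorm(100, 7, 1), 10, 10)
    rownames(v) <- sprintf("g%02d", 1:10)
    colnames(v) <- paste0("s", 1:10)
    v["g05", ] <- 3                          # constant -> variance filter
    cls <- rep(c("A", "B"), each = 5)
    v["g01", cls == "B"] <- v["g01", cls == "B"] + 10  # perfect separator
    se <- expressionMatrix(v, isGeneLevel = TRUE)
    sel <- selectFeatures(se, cls, mlConfig(nFeatures = 3))
    expect_equal(sel[1], "g01")
    expect_false("g05" %in% sel)
    ## requesting more genes than survive warns and returns all
    expect_warning(all9 <- selectFeatures(se, cls, mlConfig(nFeatures = 50)),
                   "survive")
    expect_length(all9, 9)
    expect_error(selectFeatures(se, rep("A", 10), mlConfig()),
                 class = "geolabel_ml_error")
  })
})

test_that("training and prediction behave on a separable toy", {
  toy <- toyExpression()
  cfg <- mlConfig(nFeatures = 5, minClassSize = 5, seed = 3)
  model <- trainLabelModel(toy$se, toy$labels, "sex", cfg)
  expect_s4_class(model, "TrainedModel")
  expect_equal(model@classes, c("A", "B"))
  res <- predictLabels(model, toy$se)
  expect_equal(unname(res$labels), unname(toy$labels))   # training acc 1.0
  expect_true(all(res$probabilities[cbind(seq_along(toy$labels),
                                          match(toy$labels,
                                                model@classes))] > 0.5))
  ## probabilities normalized
  expect_equal(unname(rowSums(res$probabilities)),
               rep(1, ncol(toy$se)), tolerance = 1e-9)

  ## permuting sample order leaves per-sample predictions unchanged
  perm <- withSeed(4, sample(ncol(toy$se)))
  resPerm <- predictLabels(model, toy$se[, perm])
  expect_equal(resPerm$labels, res$labels[perm])

  ## refit is deterministic
  model2 <- trainLabelModel(toy$se, toy$labels, "sex", cfg)
  expect_equal(model2@weights, model@weights)

  ## single class is fatal; age is rejected as a label type
  expect_error(trainLabelModel(toy$se, rep("A", ncol(toy$se)), "sex", cfg),
               class = "geolabel_ml_error")
  expect_error(trainLabelModel(toy$se, toy$labels, "age", cfg),
               "not predicted", class = "geolabel_ml_error")

  ## missing model genes are a named error listing them
  sub <- toy$se[setdiff(rownames(toy$se), model@selectedGenes[1]), ]
  expect_error(predictLabels(model, sub), model@selectedGenes[1],
               class = "geolabel_gene_mismatch")
})

test_that("a midpoint sample gets ~0.5 probability per class", {
  ## symmetric 2-class toy: class means +/- delta on both genes
  withSeed(9, {
    n <- 40
    cls <- rep(c("A", "B"), each = n / 2)
    delta <- ifelse(cls == "A", -1.5, 1.5)
    v <- rbind(g1 = 7 + delta + rnorm(n, 0, 0.3),
               g2 = 7 - delta + rnorm(n, 0, 0.3),
               g3 = rnorm(n, 7, 0.3))
    colnames(v) <- paste0("s", 1:n)
    se <- expressionMatrix(v, seriesIds = "GSE1", isGeneLevel = TRUE)
    model <- trainLabelModel(se, cls, "sex",
                             mlConfig(nFeatures = 2, minClassSize = 5))
    mid <- expressionMatrix(matrix(7, 3, 1,
                                   dimnames = list(paste0("g", 1:3), "m")),
                            isGeneLevel = TRUE)
    p <- predictLabels(model, mid)$probabilities
    expect_equal(unname(p[1, ]), c(0.5, 0.5), tolerance = 0.05)
  })
})

test_that("dummy baseline reflects the training distribution only", {
  one <- dummyBaseline(rep("X", 5), seed = 1)
  expect_equal(unique(unname(predictDummy(one, paste0("s", 1:20))$labels)),
               "X")
  bal <- dummyBaseline(rep(c("A", "B"), 500), seed = 2)
  draw <- predictDummy(bal, sprintf("s%04d", 1:2000))$labels
  expect_equal(mean(draw == "A"), 0.5, tolerance = 0.05)
  ## seeded reproducibility
  expect_identical(predictDummy(bal, paste0("s", 1:50))$labels,
                   predictDummy(bal, paste0("s", 1:50))$labels)
})

test_that("label combination gives text precedence and thresholds ML", {
  text <- new("SexLabel", sampleId = "S", value = "male", source = "text",
              matchedField = "title", matchedText = "sex: M",
              confidence = 1)
  expect_equal(combineLabels(text, "female", 0.99)$value, "male")
  got <- combineLabels(NULL, "liver", 0.8, threshold = 0.5)
  expect_equal(got[c("value", "source")], list(value = "liver",
                                               source = "ml"))
  expect_null(combineLabels(NULL, "liver", 0.4, threshold = 0.5))
})

test_that("model JSON serialization round-trips", {
  toy <- toyExpression()
  model <- trainLabelModel(toy$se, toy$labels, "sex",
                           mlConfig(nFeatures = 4, minClassSize = 5))
  path <- tempfile(fileext = ".json")
  writeModelJSON(model, path)
  back <- readModelJSON(path)
  expect_equal(back@weights, model@weights)
  expect_equal(back@intercepts, model@intercepts)
  expect_equal(back@classes, model@classes)
  expect_equal(predictLabels(back, toy$se)$probabilities,
               predictLabels(model, toy$se)$probabilities)
})
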
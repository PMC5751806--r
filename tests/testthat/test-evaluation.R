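test_that("experiment-stratified folds partition samples by series", {
  series <- rep(sprintf("GSE%02d", 1:10), each = 10)
  f <- makeFolds(series, k = 10, seed = 1)
  expect_equal(as.vector(table(f$sampleFold)), rep(10L, 10))
  ## no series spans two folds
  expect_true(all(tapply(f$sampleFold, series,
                         function(x) length(unique(x))) == 1))
  ## partition: every sample in exactly one fold
  expect_length(f$sampleFold, length(series))
  expect_setequal(unique(f$sampleFold), 1:10)
  ## deterministic under seed
  expect_identical(makeFolds(series, 10, 5)$seriesFold,
                   makeFolds(series, 10, 5)$seriesFold)
  expect_error(makeFolds(rep("GSE1", 30), k = 10),
               class = "geolabel_cv_error")
})

test_that("greedy packing of a skewed fixture is near-optimal", {
  series <- rep(c("big", paste0("s", 1:9)), times = c(50, rep(5, 9)))
  f <- makeFolds(series, k = 5, seed = 3)
  sizes <- tabulate(f$sampleFold, 5)
  ## exhaustive optimum for {50, 5x9} into 5 folds: one fold of 50 + the
  ## nine 5s spread 10/10/10/15 -> max 50, min 10; greedy must match the
  ## bound max <= 50 and min >= 10
  expect_equal(max(sizes), 50)
  expect_gte(min(sizes), 10)
  expect_equal(sum(sizes), length(series))
})

test_that("precision-recall matches hand-computed values", {
  ## 3-class toy confusion, hand-computed:
  ## true A(4): pred A,A,B,<abstain>; true B(3): B,B,C; true C(3): C,C,C
  yTrue <- c(rep("A", 4), rep("B", 3), rep("C", 3))
  yPred <- c("A", "A", "B", NA, "B", "B", "C", "C", "C", "C")
  pr <- precisionRecall(yTrue, yPred)
  pc <- pr$perClass
  expect_equal(pc$precision[pc$class == "A"], 1)       # 2/2
  expect_equal(pc$recall[pc$class == "A"], 0.5)        # 2/4
  expect_equal(pc$precision[pc$class == "B"], 2 / 3)
  expect_equal(pc$recall[pc$class == "B"], 2 / 3)
  expect_equal(pc$precision[pc$class == "C"], 3 / 4)
  expect_equal(pc$recall[pc$class == "C"], 1)
  ## micro: precision over 9 predictions, recall over 10 truths
  expect_equal(unname(pr$micro), c(7 / 9, 7 / 10))
  expect_equal(unname(pr$macro), c(mean(c(1, 2/3, 3/4)),
                                   mean(c(0.5, 2/3, 1))))
  expect_equal(pr$nAbstained, 1)
  ## confusion row sums equal supports
  expect_equal(unname(rowSums(pr$confusion)), c(4, 3, 3))

  ## perfect predictions
  perfect <- precisionRecall(yTrue, yTrue)
  expect_equal(unname(perfect$micro), c(1, 1))
  expect_equal(unname(perfect$macro), c(1, 1))
  ## all abstain: recall 0, precision NaN-with-flag
  allNA <- precisionRecall(c("A", "B"), c(NA, NA))
  expect_true(is.nan(allNA$micro["precision"]))
  expect_equal(unname(allNA$micro["recall"]), 0)
  expect_equal(allNA$macroUndefined, 2)
  expect_error(precisionRecall(character(), character()),
               class = "geolabel_eval_error")
})

test_that("micro P equals micro R equals accuracy without abstentions", {
  withSeed(6, for (i in 1:10) {
    k <- sample(2:5, 1)
    n <- 60
    yTrue <- sample(LETTERS[1:k], n, replace = TRUE)
    yPred <- ifelse(runif(n) < 0.6, yTrue,
                    sample(LETTERS[1:k], n, replace = TRUE))
    pr <- precisionRecall(yTrue, yPred)
    expect_identical(unname(pr$micro["precision"]),
                     unname(pr$micro["recall"]))
    expect_identical(unname(pr$micro["precision"]), pr$accuracy)
  })
})

test_that("macro metrics invariant under support rebalancing", {
  ## duplicate class-A samples with identical confusion rates: per-class
  ## rates unchanged, so macro unchanged
  yTrue <- c(rep("A", 4), rep("B", 4))
  yPred <- c("A", "A", "B", "B", "B", "B", "B", "A")
  base <- precisionRecall(yTrue, yPred)
  yTrue2 <- c(yTrue, rep("A", 4))
  yPred2 <- c(yPred, c("A", "A", "B", "B"))
  scaled <- precisionRecall(yTrue2, yPred2)
  expect_equal(scaled$macro["recall"], base$macro["recall"])
  expect_equal(unname(scaled$perClass$recall),
               unname(base$perClass$recall))
})

test_that("topM and support floor restrict the evaluated classes", {
  yTrue <- c(rep("big", 10), rep("mid", 5), rep("tiny", 2))
  yPred <- yTrue
  pr <- precisionRecall(yTrue, yPred, topM = 2)
  expect_setequal(pr$perClass$class, c("big", "mid"))
  pr2 <- precisionRecall(yTrue, yPred, supportFloor = 5)
  expect_false("tiny" %in% pr2$perClass$class)
})

test_that("age error statistics are exact on known pairs", {
  expect_equal(ageError(c(1, 2, 3), c(1, 2, 3)),
               list(mad = 0, mse = 0, withinOneMonth = 1,
                    nUsed = 3, nMissing = 0))
  ## single pair off by half a month is still within one month
  e <- ageError(30, 30 + 0.5 / 12)
  expect_equal(e$withinOneMonth, 1)
  ## printed arithmetic example
  e2 <- ageError(c(30, 40), c(30, 55))
  expect_equal(e2$mad, 7.5)
  expect_equal(e2$mse, 112.5)
  expect_equal(e2$withinOneMonth, 0.5)
  ## missing predictions excluded and counted
  e3 <- ageError(c(1, 2, 3), c(1, NA, 3))
  expect_equal(e3$nUsed, 2)
  expect_equal(e3$nMissing, 1)
  expect_error(ageError(1, NA_real_), class = "geolabel_eval_error")
})

test_that("distance profile concentrates at 0/1 for perfect/parent labels", {
  g <- fixtureOntology()
  terms <- c("TOY:0000004", "TOY:0000005", "TOY:0000011")
  perfect <- distanceProfile(g, terms, terms, nRandom = 50, seed = 2)
  expect_true(all(perfect$distances == 0))
  parents <- vapply(terms, function(t)
    g@parents[[match(t, termIds(g))]][1], "")
  offByOne <- distanceProfile(g, terms, parents, nRandom = 50, seed = 2)
  expect_true(all(offByOne$distances == 1))
  expect_warning(
    skipped <- distanceProfile(g, c(terms, "NOPE:1"),
                               c(terms, "TOY:0000004"), seed = 1),
    "skipped")
  expect_equal(skipped$nSkipped, 1)
})

test_that("random tissue predictions are indistinguishable from baseline", {
  g <- genToyOntology(nTerms = 40, seed = 12)
  n <- 400
  ids <- termIds(g)
  pairs <- withSeed(13, cbind(sample(ids, n, replace = TRUE),
                              sample(ids, n, replace = TRUE)))
  prof <- distanceProfile(g, pairs[, 1], pairs[, 2], nRandom = n, seed = 14)
  tab <- table(factor(prof$distances, levels = 0:max(c(prof$distances,
                                                       prof$random))),
               rep("obs", n))
  rtab <- table(factor(prof$random, levels = rownames(tab)))
  m <- cbind(obs = as.vector(tab), rand = as.vector(rtab))
  m <- m[rowSums(m) > 0, , drop = FALSE]
  p <- suppressWarnings(stats::chisq.test(m)$p.value)
  expect_gt(p, 0.01)
})

test_that("cross-validation never leaks series into a fold's training", {
  toy <- toyExpression(nPer = 20, nSeries = 8)
  folds <- makeFolds(seriesIds(toy$se), k = 4, seed = 5)
  cv <- crossValidate(toy$se, toy$labels, "sex",
                      mlConfig(nFeatures = 4, minClassSize = 5, seed = 5),
                      folds = folds)
  pred <- cv$predictions
  ## samples of one series share a fold by construction
  expect_true(all(tapply(pred$fold, pred$series_id,
                         function(x) length(unique(x))) == 1))
  ## separable toy: near-perfect pooled metrics
  expect_gt(cv$metrics$accuracy, 0.9)
  expect_gt(cv$macroAUC, 0.95)
})
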
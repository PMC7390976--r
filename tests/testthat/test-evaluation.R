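test_that("confusion counts enumerate correctly", {
  cm <- confusionCounts(c("insufficient", "insufficient", "sufficient"),
                        c("insufficient", "sufficient", "sufficient"))
  expect_equal(cm, c(tp = 1L, fp = 0L, tn = 1L, fn = 1L))
  a <- rep(c("insufficient", "sufficient"), 3)
  expect_equal(confusionCounts(a, a)[c("fp", "fn")], c(fp = 0L, fn = 0L))
  expect_error(confusionCounts(a, a[-1]), "equal length")
  expect_error(confusionCounts("bogus", "insufficient"), "labels")
})

test_that("random label pairs match the independent counting oracle", {
  set.seed(101)
  a <- sample(c("insufficient", "sufficient"), 100, replace = TRUE)
  p <- sample(c("insufficient", "sufficient"), 100, replace = TRUE)
  bf <- bruteForceMetrics(a, p)
  cm <- confusionCounts(a, p)
  expect_equal(unname(cm), c(bf$tp, bf$fp, bf$tn, bf$fn))
  expect_equal(accuracyScore(cm), bf$accuracy)
  expect_equal(precisionScore(cm), bf$precision)
  expect_equal(recallScore(cm), bf$recall)
  expect_equal(mccScore(cm), bf$mcc)
})

test_that("metrics agree with hand-evaluated formulas", {
  cm <- c(tp = 27, fp = 3, tn = 11, fn = 1)
  expect_equal(accuracyScore(cm), 38 / 42)
  expect_equal(precisionScore(cm), 0.90)
  expect_equal(recallScore(cm), 27 / 28)
  expect_equal(mccScore(cm), 294 / sqrt(30 * 28 * 14 * 12))
  perfect <- c(tp = 5, fp = 0, tn = 5, fn = 0)
  expect_equal(accuracyScore(perfect), 1)
  expect_equal(precisionScore(perfect), 1)
  expect_equal(recallScore(perfect), 1)
  expect_equal(mccScore(perfect), 1)
})

test_that("all 256 labelings of four items match brute force", {
  labs <- c("insufficient", "sufficient")
  grid <- expand.grid(a1 = labs, a2 = labs, a3 = labs, a4 = labs,
                      p1 = labs, p2 = labs, p3 = labs, p4 = labs,
                      stringsAsFactors = FALSE)
  expect_equal(nrow(grid), 256L)
  for (i in seq_len(nrow(grid))) {
    a <- unlist(grid[i, 1:4]); p <- unlist(grid[i, 5:8])
    bf <- bruteForceMetrics(a, p)
    cm <- confusionCounts(a, p)
    expect_equal(accuracyScore(cm), bf$accuracy)
    expect_equal(suppressWarnings(precisionScore(cm)), bf$precision)
    expect_equal(suppressWarnings(recallScore(cm)), bf$recall)
    expect_equal(mccScore(cm), bf$mcc)
  }
})

test_that("MCC is invariant under swapping the positive class convention", {
  set.seed(103)
  for (k in 1:20) {
    a <- sample(c("insufficient", "sufficient"), 12, replace = TRUE)
    p <- sample(c("insufficient", "sufficient"), 12, replace = TRUE)
    swap <- function(x) ifelse(x == "insufficient", "sufficient", "insufficient")
    expect_equal(mccScore(confusionCounts(a, p)),
                 mccScore(confusionCounts(swap(a), swap(p))))
  }
})

test_that("degenerate classifiers follow the stated conventions", {
  # all-positive prediction: recall 1, accuracy = prevalence, MCC 0
  a <- c(rep("insufficient", 8), rep("sufficient", 4))
  p <- rep("insufficient", 12)
  cm <- confusionCounts(a, p)
  expect_equal(recallScore(cm), 1)
  expect_equal(accuracyScore(cm), 8 / 12)
  expect_equal(precisionScore(cm), 8 / 12)
  expect_equal(mccScore(cm), 0)
  # perfect anticorrelation on a balanced set
  b <- rep(c("insufficient", "sufficient"), 5)
  expect_equal(mccScore(confusionCounts(b, ifelse(b == "insufficient",
                                                  "sufficient",
                                                  "insufficient"))), -1)
  # undefined precision/recall surface as NA with a warning, never 0
  noPos <- confusionCounts(rep("sufficient", 3), rep("sufficient", 3))
  expect_warning(pr <- precisionScore(noPos), "undefined")
  expect_true(is.na(pr))
  expect_warning(rc <- recallScore(noPos), "undefined")
  expect_true(is.na(rc))
})

test_that("leave-one-out CV predicts every run from the others", {
  co <- makeCohortTable(n = 8, seed = 107)
  cv <- looCv(co$table, "rf_regressor", seed = 1)
  expect_s4_class(cv, "CvResult")
  expect_equal(cvScheme(cv), "loo")
  expect_length(cvPredicted(cv), 8L)
  expect_identical(runIds(cv), runIds(co$table))
  m <- cvMetrics(cv)
  expect_equal(unname(sum(m$counts)), 8)
  # no leakage: altering run i's outcome leaves its own LOO prediction alone
  cm <- cmContent(co$table)
  tweaked <- co$table
  SummarizedExperiment::colData(tweaked)$cmContent[3] <-
    if (cm[3] < 90) 99 else 10
  cv2 <- looCv(tweaked, "rf_regressor", seed = 1)
  expect_identical(cvPredicted(cv)[3], cvPredicted(cv2)[3])
  expect_error(looCv(co$table[, 1:3], "rf_regressor"), "at least 5")
})

test_that("Monte-Carlo CV produces per-trial reports and mean aggregation", {
  co <- makeCohortTable(n = 16, seed = 109)
  cv <- mcCv(co$table, "rf_regressor", testSize = 5, trials = 10, seed = 2)
  expect_length(cvPerTrial(cv), 10L)
  accs <- vapply(cvPerTrial(cv), `[[`, numeric(1), "accuracy")
  expect_equal(cvMetrics(cv)$accuracy, mean(accs))
  expect_length(cvActual(cv), 50L)   # 10 trials x 5 held-out runs
  # degenerate split: a single trial holding out most of the cohort
  cv1 <- mcCv(co$table, "rf_regressor", testSize = 11, trials = 1, seed = 3)
  expect_length(cvActual(cv1), 11L)
  expect_error(mcCv(co$table, testSize = 16), "smaller")
  # reproducibility
  cvA <- mcCv(co$table, "rf_regressor", testSize = 5, trials = 4, seed = 9)
  cvB <- mcCv(co$table, "rf_regressor", testSize = 5, trials = 4, seed = 9)
  expect_identical(cvPredicted(cvA), cvPredicted(cvB))
})

test_that("hold-out evaluation trains once and respects disjointness", {
  co <- makeCohortTable(n = 24, seed = 113)
  train <- co$table[, 1:18]
  test <- co$table[, 19:24]
  hv <- holdoutEvaluate(train, test, "rf_regressor", seed = 1)
  expect_equal(cvScheme(hv), "holdout")
  expect_length(cvPredicted(hv), 6L)
  expect_error(holdoutEvaluate(train, co$table[, 10:20], "rf_regressor"),
               "share run ids")
})

test_that("a test set without positives reports recall as missing", {
  co <- makeCohortTable(n = 30, seed = 127)
  cm <- cmContent(co$table)
  suffIdx <- which(cm >= 90)
  train <- co$table[, setdiff(seq_len(30), suffIdx[1:3])]
  test <- co$table[, suffIdx[1:3]]
  expect_warning(hv <- holdoutEvaluate(train, test, "rf_regressor", seed = 1),
                 "undefined")
  expect_true(is.na(cvMetrics(hv)$recall))
})
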
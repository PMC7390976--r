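## Classification evaluation: confusion matrix, the four performance metrics
##   accuracy  = (TP + TN) / (TP + TN + FP + FN)
##   precision = TP / (TP + FP)
##   recall    = TP / (TP + FN)
##   MCC       = (TP*TN - FP*FN) /
##               sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))
## with `insufficient` as the positive class, and the three cross-validation
## protocols (leave-one-out, Monte-Carlo, hold-out).

.asClassFactor <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (!all(x %in% .CLASS_LEVELS))
    stop("labels must be 'insufficient' or 'sufficient'")
  factor(x, levels = .CLASS_LEVELS)
}

#' Confusion counts
#'
#' Tallies true/false positives/negatives of predicted against actual class
#' labels, with `insufficient` (process failure) as the positive class.
#'
#' @param actual,predicted Equal-length label vectors/factors with values
#'   `insufficient` / `sufficient`.
#' @return Named integer vector `c(tp, fp, tn, fn)`.
#' @examples
#' confusionCounts(c("insufficient", "insufficient", "sufficient"),
#'                 c("insufficient", "sufficient", "sufficient"))
#' @export
confusionCounts <- function(actual, predicted) {
  actual <- .asClassFactor(actual); predicted <- .asClassFactor(predicted)
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length")
  if (!length(actual)) stop("need at least one label pair")
  c(tp = sum(actual == "insufficient" & predicted == "insufficient"),
    fp = sum(actual == "sufficient" & predicted == "insufficient"),
    tn = sum(actual == "sufficient" & predicted == "sufficient"),
    fn = sum(actual == "insufficient" & predicted == "sufficient"))
}

.checkCounts <- function(cm) {
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(cm)))
  if (any(cm < 0)) stop("negative confusion counts")
  cm
}

#' Classification performance metrics
#'
#' @description
#' `accuracyScore()`, `precisionScore()` and `recallScore()` compute the
#' proportion of correct classifications, the proportion of predicted
#' positives that are truly positive, and the proportion of actual positives
#' identified, respectively. `mccScore()` computes the Matthews correlation
#' coefficient between predicted and actual labels.
#'
#' Conventions: an all-zero matrix errors (nothing was evaluated); an empty
#' predicted-positive or actual-positive set makes precision/recall
#' undefined, returned as `NA` with a warning; a zero factor in the MCC
#' denominator yields `MCC = 0` (an uninformative classifier, e.g. one
#' predicting a single class, has no correlation with the truth).
#'
#' @param cm Named counts from [confusionCounts()].
#' @return A single number (`NA` where undefined).
#' @examples
#' cm <- c(tp = 27, fp = 3, tn = 11, fn = 1)
#' accuracyScore(cm)   # 38/42
#' mccScore(cm)        # ~0.783
#' @export
accuracyScore <- function(cm) {
  cm <- .checkCounts(cm)
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  unname((cm["tp"] + cm["tn"]) / n)
}

#' @rdname accuracyScore
#' @export
precisionScore <- function(cm) {
  cm <- .checkCounts(cm)
  d <- cm["tp"] + cm["fp"]
  if (d == 0) { warning("no predicted positives: precision undefined")
                return(NA_real_) }
  unname(cm["tp"] / d)
}

#' @rdname accuracyScore
#' @export
recallScore <- function(cm) {
  cm <- .checkCounts(cm)
  d <- cm["tp"] + cm["fn"]
  if (d == 0) { warning("no actual positives: recall undefined")
                return(NA_real_) }
  unname(cm["tp"] / d)
}

#' @rdname accuracyScore
#' @export
mccScore <- function(cm) {
  cm <- .checkCounts(cm)
  tp <- as.numeric(cm["tp"]); fp <- as.numeric(cm["fp"])
  tn <- as.numeric(cm["tn"]); fn <- as.numeric(cm["fn"])
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  ((tp * tn) - (fp * fn)) / sqrt(den)
}

#' Metrics report from label vectors
#'
#' @param actual,predicted Label vectors (see [confusionCounts()]).
#' @return List with `counts` and the four metrics.
#' @export
metricsReport <- function(actual, predicted) {
  cm <- confusionCounts(actual, predicted)
  list(counts = cm,
       accuracy = accuracyScore(cm),
       precision = precisionScore(cm),
       recall = recallScore(cm),
       mcc = mccScore(cm))
}

## Shared fold worker: train on `trainIdx`, predict classes for `testIdx`.
## Preprocessing (imputation, standardisation) is refit inside each fold by
## trainModel(); optional selection can also be refit per fold.
.foldPredict <- function(table, trainIdx, testIdx, backend, features,
                         selection, threshold, seed, settings) {
  sub <- table[, trainIdx]
  if (!is.null(selection)) {
    extra <- if (selection$method %in% c("rf", "gpr_ard"))
      list(seed = .childSeed(seed, 555L)) else list()
    sr <- do.call(selectFeatures,
                  c(list(table = sub, method = selection$method), extra))
    features <- if (selection$method == "pca") sr else selectedFeatures(sr)
  }
  if (is(features, "SelectionResult") && selectionMethod(features) == "pca") {
    pcs <- pcProject(table, features)
    model <- .trainOnMatrix(pcs[trainIdx, , drop = FALSE],
                            cmContent(table)[trainIdx], backend, threshold,
                            seed, settings)
    return(.predictOnMatrix(model, pcs[testIdx, , drop = FALSE]))
  }
  model <- trainModel(sub, backend, features = features,
                      threshold = threshold, seed = seed, settings = settings)
  predictClass(model, table[, testIdx])
}

## Matrix-level train/predict used for principal-component inputs, whose
## column names live outside the feature grammar.
.trainOnMatrix <- function(X, y, backend, threshold, seed, settings) {
  ft <- FeatureTable(X, cmContent = y)
  trainModel(ft, backend, features = NULL, threshold = threshold,
             seed = seed, settings = settings)
}

.predictOnMatrix <- function(model, X) {
  predictClass(model, X)
}

#' Leave-one-out cross-validation
#'
#' Each run is predicted by a model trained on all other runs; imputation,
#' standardisation and (optionally) feature selection are refit within each
#' fold. Aggregate metrics are computed over the n held-out predictions.
#'
#' @param table A [FeatureTable] with outcome (n >= 5).
#' @param backend Model backend, see [trainModel()].
#' @param features Feature subset: character vector, a
#'   [SelectionResult-class] (a `pca` result trains on its retained
#'   components, refitting the projection per fold), or `NULL` for all.
#' @param selection Optional list `list(method = ...)` to refit feature
#'   selection inside every fold instead of using a fixed subset.
#' @param threshold Classification threshold (percent).
#' @param seed Integer seed (fold models derive their seeds from it).
#' @param settings Backend settings.
#' @return A [CvResult-class] with scheme `"loo"`.
#' @export
looCv <- function(table, backend = "rf_classifier", features = NULL,
                  selection = NULL, threshold = 90, seed = 1L,
                  settings = list()) {
  n <- ncol(table)
  if (n < 5L) stop("need at least 5 runs for leave-one-out CV")
  actual <- classifyCm(cmContent(table), threshold)
  predicted <- factor(rep(NA_character_, n), levels = .CLASS_LEVELS)
  for (i in seq_len(n)) {
    predicted[i] <- tryCatch(
      .foldPredict(table, setdiff(seq_len(n), i), i, backend, features,
                   selection, threshold, .childSeed(seed, i), settings),
      error = function(e) stop("LOO fold ", i, " (run ", colnames(table)[i],
                               ") failed: ", conditionMessage(e)))
  }
  .CvResult("loo", colnames(table), actual, predicted,
            metricsReport(actual, predicted), seed = seed)
}

#' Monte-Carlo cross-validation
#'
#' In each trial a random validation set of `testSize` runs is held out, the
#' model is trained on the remainder and the trial's metrics are computed on
#' the held-out runs. The aggregate report averages the per-trial metrics
#' (`NA` metrics excluded with a warning); pooled counts over all trials are
#' also attached as `pooled`.
#'
#' @inheritParams looCv
#' @param testSize Held-out runs per trial (the emulated protocol uses 5).
#' @param trials Number of trials (the emulated protocol uses 40).
#' @return A [CvResult-class] with scheme `"monte_carlo"` and per-trial
#'   reports in `cvPerTrial()`.
#' @export
mcCv <- function(table, backend = "rf_classifier", features = NULL,
                 selection = NULL, testSize = 5L, trials = 40L,
                 threshold = 90, seed = 1L, settings = list()) {
  n <- ncol(table)
  if (testSize >= n) stop("testSize must be smaller than the number of runs")
  if (trials < 1L) stop("trials must be >= 1")
  actualAll <- classifyCm(cmContent(table), threshold)
  testSets <- .withSeed(seed,
    lapply(seq_len(trials), function(b) sample.int(n, testSize)))
  perTrial <- vector("list", trials)
  allActual <- character(0); allPred <- character(0); allIds <- character(0)
  for (b in seq_len(trials)) {
    testIdx <- testSets[[b]]
    pred <- .foldPredict(table, setdiff(seq_len(n), testIdx), testIdx,
                         backend, features, selection, threshold,
                         .childSeed(seed, 1000L + b), settings)
    perTrial[[b]] <- metricsReport(actualAll[testIdx], pred)
    allActual <- c(allActual, as.character(actualAll[testIdx]))
    allPred <- c(allPred, as.character(pred))
    allIds <- c(allIds, colnames(table)[testIdx])
  }
  agg <- lapply(c(accuracy = "accuracy", precision = "precision",
                  recall = "recall", mcc = "mcc"), function(m) {
    v <- vapply(perTrial, `[[`, numeric(1), m)
    if (anyNA(v))
      warning("metric '", m, "' undefined in ", sum(is.na(v)),
              " trial(s); averaged over the rest")
    mean(v, na.rm = TRUE)
  })
  agg$counts <- confusionCounts(allActual, allPred)
  agg$pooled <- metricsReport(allActual, allPred)
  .CvResult("monte_carlo", allIds, .asClassFactor(allActual),
            .asClassFactor(allPred), agg, perTrial = perTrial, seed = seed)
}

#' Hold-out evaluation
#'
#' Trains once on the training table (with its own selection/imputation) and
#' reports metrics on a disjoint test table, emulating the 42-train /
#' 16-test protocol.
#'
#' @param trainTable,testTable [FeatureTable]s with disjoint run ids.
#' @inheritParams looCv
#' @return A [CvResult-class] with scheme `"holdout"`.
#' @export
holdoutEvaluate <- function(trainTable, testTable, backend = "rf_classifier",
                            features = NULL, threshold = 90, seed = 1L,
                            settings = list()) {
  if (length(intersect(runIds(trainTable), runIds(testTable))))
    stop("train and test tables share run ids")
  if (is(features, "SelectionResult") && selectionMethod(features) == "pca") {
    pcsTrain <- pcProject(trainTable, features)
    model <- .trainOnMatrix(pcsTrain, cmContent(trainTable), backend,
                            threshold, seed, list())
    pred <- .predictOnMatrix(model, pcProject(testTable, features))
  } else {
    model <- trainModel(trainTable, backend, features = features,
                        threshold = threshold, seed = seed)
    pred <- predictClass(model, testTable)
  }
  actual <- classifyCm(cmContent(testTable), threshold)
  .CvResult("holdout", runIds(testTable), actual, pred,
            metricsReport(actual, pred), seed = seed)
}
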
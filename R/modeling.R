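## Predictive models of the day-10 cardiomyocyte content and the 90%
## classification rule. MARS, random-forest and GP regressors predict the
## CM percentage, which is thresholded into the binary classes; the direct
## random-forest classifier votes on the binary labels instead.

.CLASS_LEVELS <- c("insufficient", "sufficient")

#' Classify a CM content value
#'
#' A run is `sufficient` when its (predicted or measured) cardiomyocyte
#' content is at or above the threshold, `insufficient` otherwise;
#' `insufficient` is the positive class throughout the package.
#'
#' @param cmPercent CM content in percent, in `[0, 100]` (vectorised).
#' @param threshold Classification threshold in percent (default 90).
#' @return Factor with levels `insufficient`, `sufficient`.
#' @examples
#' classifyCm(c(92, 89.9, 90))   # sufficient, insufficient, sufficient
#' @export
classifyCm <- function(cmPercent, threshold = 90) {
  if (any(is.na(cmPercent)) || any(cmPercent < 0) || any(cmPercent > 100))
    stop("cmPercent must lie in [0, 100]")
  if (threshold <= 0 || threshold >= 100) stop("threshold must lie in (0, 100)")
  factor(ifelse(cmPercent >= threshold, "sufficient", "insufficient"),
         levels = .CLASS_LEVELS)
}

.modelMatrix <- function(newdata, features) {
  if (is(newdata, "FeatureTable")) newdata <- featureValues(newdata)
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1,
                                               dimnames = list(NULL,
                                                               names(newdata)))
  missing <- setdiff(features, colnames(newdata))
  if (length(missing))
    stop("prediction input lacks training feature(s): ",
         paste(missing, collapse = ", "))
  newdata[, features, drop = FALSE]
}

.applyPreprocess <- function(X, pp) {
  if (anyNA(X))
    for (j in seq_len(ncol(X)))
      X[is.na(X[, j]), j] <- pp$medians[colnames(X)[j]]
  if (!is.null(pp$center))
    X <- scale(X, center = pp$center, scale = pp$scale)
  X
}

#' Train a CM-content predictor
#'
#' Fits one of the four backends on a feature table: `"mars"` (hinge-basis
#' regression with GCV pruning), `"rf_regressor"` / `"rf_classifier"`
#' (random forests with 5 trees by default), or `"gpr"` (Gaussian-process
#' regression with an isotropic RBF kernel, hyperparameters by marginal
#' likelihood with 5 fixed-seed restarts). Per-feature training medians are
#' stored for imputation at prediction time; the GP additionally stores the
#' training standardisation. Training is deterministic given the seed.
#'
#' @param table A [FeatureTable] whose `colData` carries the outcome.
#' @param backend One of `"mars"`, `"rf_regressor"`, `"rf_classifier"`,
#'   `"gpr"`.
#' @param features Feature subset to train on: a character vector, a
#'   [SelectionResult-class] (its selected features), or `NULL` for all.
#' @param threshold Classification threshold in percent.
#' @param seed Integer seed.
#' @param settings Backend settings; `ntree` (default 5) for the forests,
#'   `restarts`/`maxit` for the GP, `maxTerms`/`nKnots`/`penalty` for MARS.
#' @return A `CmModel` object.
#' @examples
#' \donttest{
#' cohort <- generateCohort(syntheticConfig(nRuns = 12, seed = 5))
#' ft <- buildFeatureTable(cohort$runs, cutoff = "dd7")
#' m <- trainModel(ft, "rf_regressor", seed = 1)
#' predictCm(m, ft)[1:3]
#' }
#' @export
trainModel <- function(table, backend = c("rf_classifier", "rf_regressor",
                                          "gpr", "mars"),
                       features = NULL, threshold = 90, seed = 1L,
                       settings = list()) {
  backend <- match.arg(backend)
  if (is(features, "SelectionResult")) {
    if (selectionMethod(features) == "pca")
      stop("train on PC scores via pcProject(), not a pca SelectionResult")
    features <- selectedFeatures(features)
  }
  X <- featureValues(table)
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(X))
    if (length(missing))
      stop("unknown feature(s): ", paste(missing, collapse = ", "))
    X <- X[, features, drop = FALSE]
  }
  y <- cmContent(table)
  if (nrow(X) < 5L) stop("need at least 5 training runs")
  if (any(is.na(y))) stop("all training runs need an endpoint CM content")
  if (stats::sd(y) == 0) stop("constant outcome")
  pp <- list(medians = apply(X, 2L, stats::median, na.rm = TRUE))
  X <- .applyPreprocess(X, pp)
  if (any(!is.finite(X)))
    stop("non-finite feature values after imputation")
  fit <- switch(backend,
    mars = {
      s <- utils::modifyList(list(maxTerms = 21L, nKnots = 11L, penalty = 2),
                             settings)
      list(mars = .marsFit(X, y, maxTerms = s$maxTerms, nKnots = s$nKnots,
                           penalty = s$penalty))
    },
    rf_regressor = {
      ntree <- settings$ntree %||% 5L
      list(rf = .withSeed(seed,
        randomForest::randomForest(x = X, y = y, ntree = ntree)))
    },
    rf_classifier = {
      ntree <- settings$ntree %||% 5L
      labels <- classifyCm(y, threshold)
      if (nlevels(droplevels(labels)) < 2L)
        stop("training outcomes fall in a single class")
      list(rf = .withSeed(seed,
        randomForest::randomForest(x = X, y = labels, ntree = ntree)))
    },
    gpr = {
      s <- utils::modifyList(list(restarts = 5L, maxit = 200L), settings)
      ctr <- colMeans(X); scl <- apply(X, 2L, stats::sd)
      scl[scl == 0] <- 1
      pp$center <- ctr; pp$scale <- scl
      Z <- scale(X, center = ctr, scale = scl)
      list(gp = .gpFit(Z, y, ard = FALSE, restarts = s$restarts, seed = seed,
                       maxit = s$maxit))
    })
  new("CmModel", backend = backend, fit = fit, features = colnames(X),
      threshold = threshold, seed = as.numeric(seed), preprocess = pp)
}

#' @rdname predictCm
#' @export
setMethod("predictCm", "CmModel", function(model, newdata, ...) {
  X <- .modelMatrix(newdata, model@features)
  X <- .applyPreprocess(X, model@preprocess)
  raw <- switch(model@backend,
    mars = .marsPredict(model@fit$mars, X),
    rf_regressor = as.vector(stats::predict(model@fit$rf, X)),
    rf_classifier = stop("predictCm() is undefined for the direct classifier backend"),
    gpr = .gpPredict(model@fit$gp, X))
  out <- pmin(100, pmax(0, raw))
  names(out) <- rownames(X)
  out
})

#' @rdname predictCm
#' @export
setMethod("predictClass", "CmModel", function(model, newdata, ...) {
  if (model@backend == "rf_classifier") {
    X <- .modelMatrix(newdata, model@features)
    X <- .applyPreprocess(X, model@preprocess)
    prob <- stats::predict(model@fit$rf, X, type = "prob")
    out <- factor(ifelse(prob[, "insufficient"] >= 0.5,
                         "insufficient", "sufficient"),
                  levels = .CLASS_LEVELS)
    names(out) <- rownames(X)
    return(out)
  }
  classifyCm(predictCm(model, newdata), model@threshold)
})
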
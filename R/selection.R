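## Feature-selection methods: correlation ranking, principal components,
## random-forest impurity importance, GP-ARD sensitivity and MARS basis
## membership. Each returns a SelectionResult with per-feature scores and
## the selected subset (or the retained principal components).

#' Pearson and Spearman correlation
#'
#' Thin validated wrappers around the product-moment and rank correlation
#' coefficients used for univariate feature screening. Both error on
#' constant input, where the coefficient is undefined.
#'
#' @param x,y Equal-length numeric vectors (n >= 3), neither constant.
#' @return The correlation coefficient in `[-1, 1]`.
#' @examples
#' pearsonCorrelation(1:3, c(2, 4, 6))    # 1
#' spearmanCorrelation(1:4, (1:4)^3)      # 1 (monotone)
#' @export
pearsonCorrelation <- function(x, y) {
  .checkCorArgs(x, y)
  stats::cor(x, y, method = "pearson")
}

#' @rdname pearsonCorrelation
#' @export
spearmanCorrelation <- function(x, y) {
  .checkCorArgs(x, y)
  stats::cor(x, y, method = "spearman")
}

.checkCorArgs <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  invisible(TRUE)
}

## Common preparation: feature matrix, outcome, zero-variance drop.
.selectionInputs <- function(table, requireOutcome = TRUE, impute = TRUE) {
  X <- featureValues(table)
  y <- cmContent(table)
  if (requireOutcome && all(is.na(y)))
    stop("feature table carries no outcome (cmContent all NA)")
  if (requireOutcome && stats::sd(y, na.rm = TRUE) == 0)
    stop("degenerate outcome: cmContent is constant")
  if (impute && anyNA(X)) {
    med <- apply(X, 2L, stats::median, na.rm = TRUE)
    for (j in which(colSums(is.na(X)) > 0))
      X[is.na(X[, j]), j] <- med[j]
  }
  sds <- apply(X, 2L, stats::sd)
  zv <- !is.finite(sds) | sds == 0
  if (any(zv)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(X)[zv], collapse = ", "))
    X <- X[, !zv, drop = FALSE]
  }
  list(X = X, y = y)
}

#' Correlation-based feature selection
#'
#' Scores every feature by its Pearson or Spearman correlation with the
#' endpoint CM content; features with `|r|` at or above the threshold are
#' selected, ordered by decreasing `|r|`.
#'
#' @param table A [FeatureTable] with outcome.
#' @param method `"pearson"` or `"spearman"`.
#' @param threshold Absolute-correlation selection cutoff.
#' @return A [SelectionResult-class].
#' @export
correlationSelect <- function(table, method = c("pearson", "spearman"),
                              threshold = 0.3) {
  method <- match.arg(method)
  inp <- .selectionInputs(table)
  r <- apply(inp$X, 2L, stats::cor, y = inp$y, method = method)
  sel <- names(sort(abs(r[abs(r) >= threshold]), decreasing = TRUE))
  .SelectionResult(method, scores = r, selected = sel,
                   settings = list(threshold = threshold))
}

#' Principal-component reduction
#'
#' Standardises (z-scores) the features, performs PCA and retains the
#' smallest number of leading components whose cumulative explained-variance
#' ratio reaches `varianceTarget` (0.94 by default, the retention level used
#' for the modelled process).
#'
#' @param table A [FeatureTable] (outcome not required).
#' @param varianceTarget Fraction of variance to retain, in (0, 1].
#' @return A [SelectionResult-class] with method `"pca"`; `details` carries
#'   `loadings`, `explainedVariance`, `nComponents` and the standardisation
#'   constants; `selected` names the retained components.
#' @examples
#' \donttest{
#' cohort <- generateCohort(syntheticConfig(nRuns = 12, seed = 3))
#' ft <- buildFeatureTable(cohort$runs, cutoff = "dd7")
#' pcaReduce(ft)
#' }
#' @export
pcaReduce <- function(table, varianceTarget = 0.94) {
  if (varianceTarget <= 0 || varianceTarget > 1)
    stop("varianceTarget must lie in (0, 1]")
  inp <- .selectionInputs(table, requireOutcome = FALSE)
  if (nrow(inp$X) < 2L) stop("need at least 2 runs for PCA")
  ctr <- colMeans(inp$X)
  scl <- apply(inp$X, 2L, stats::sd)
  Z <- scale(inp$X, center = ctr, scale = scl)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  nComp <- which(cumsum(evr) >= varianceTarget - 1e-12)[1L]
  scores <- evr
  names(scores) <- colnames(pc$x)
  .SelectionResult("pca",
    scores = scores,
    selected = colnames(pc$x)[seq_len(nComp)],
    settings = list(varianceTarget = varianceTarget),
    details = list(loadings = pc$rotation, explainedVariance = evr,
                   nComponents = nComp, center = ctr, scale = scl))
}

#' Project runs onto retained principal components
#'
#' @param table A [FeatureTable] with the same features the PCA was fit on.
#' @param pca A [SelectionResult-class] from [pcaReduce()].
#' @return Matrix of PC scores, runs x retained components.
#' @export
pcProject <- function(table, pca) {
  stopifnot(selectionMethod(pca) == "pca")
  d <- selectionDetails(pca)
  X <- featureValues(table)[, names(d$center), drop = FALSE]
  if (anyNA(X)) {
    for (j in seq_len(ncol(X)))
      X[is.na(X[, j]), j] <- d$center[j]
  }
  Z <- scale(X, center = d$center, scale = d$scale)
  (Z %*% d$loadings)[, seq_len(d$nComponents), drop = FALSE]
}

#' Random-forest importance selection
#'
#' Fits a seeded regression forest of the CM content on all features and
#' scores each feature by its total impurity (node RSS) decrease, normalised
#' to sum to one; features scoring at or above the mean importance are
#' selected.
#'
#' @param table A [FeatureTable] with outcome.
#' @param ntree Trees in the selection forest.
#' @param seed Integer seed.
#' @return A [SelectionResult-class] with method `"rf"`.
#' @export
rfSelect <- function(table, ntree = 200L, seed = 1L) {
  inp <- .selectionInputs(table)
  rf <- .withSeed(seed,
    randomForest::randomForest(x = inp$X, y = inp$y, ntree = ntree,
                               importance = FALSE))
  imp <- randomForest::importance(rf, type = 2)[, 1L]
  if (sum(imp) > 0) imp <- imp / sum(imp)
  sel <- names(sort(imp[imp >= mean(imp)], decreasing = TRUE))
  .SelectionResult("rf", scores = imp, selected = sel,
                   settings = list(ntree = ntree, seed = seed,
                                   rule = "importance >= mean importance"))
}

#' GP-ARD sensitivity selection
#'
#' Fits a Gaussian-process regression with an anisotropic RBF kernel (one
#' length-scale per feature, optimised by marginal likelihood: automatic
#' relevance determination) on z-scored features, then sharpens the ARD
#' ranking by a sensitivity analysis: each feature's score is the mean
#' squared partial derivative of the posterior mean over the training
#' points (central finite differences). Features scoring at least
#' `threshold` times the maximum sensitivity are selected.
#'
#' @param table A [FeatureTable] with outcome.
#' @param threshold Fraction of the maximum sensitivity, default 0.1.
#' @param seed Integer seed for optimiser restarts.
#' @param restarts,maxit Optimiser restarts and iteration cap.
#' @return A [SelectionResult-class] with method `"gpr_ard"`; `details`
#'   carries the optimised length-scales.
#' @export
gprArdSelect <- function(table, threshold = 0.1, seed = 1L, restarts = 1L,
                         maxit = 150L) {
  inp <- .selectionInputs(table)
  Z <- scale(inp$X)
  fit <- .gpFit(Z, inp$y, ard = TRUE, restarts = restarts, seed = seed,
                maxit = maxit)
  s <- .gpSensitivity(fit)
  names(s) <- colnames(Z)
  sel <- names(sort(s[s >= threshold * max(s)], decreasing = TRUE))
  .SelectionResult("gpr_ard", scores = s, selected = sel,
                   settings = list(threshold = threshold, seed = seed,
                                   restarts = restarts),
                   details = list(lengthScales =
                                    structure(fit$ell, names = colnames(Z))))
}

#' MARS basis-membership selection
#'
#' Fits a MARS model (forward hinge growth, GCV pruning) of the CM content
#' on the raw features; the selected features are those appearing in at
#' least one retained non-constant basis function. Scores are the number of
#' retained basis functions per feature.
#'
#' @param table A [FeatureTable] with outcome.
#' @param maxTerms,nKnots,penalty Forward/pruning controls (see the methods
#'   vignette).
#' @return A [SelectionResult-class] with method `"mars"`.
#' @export
marsSelect <- function(table, maxTerms = 21L, nKnots = 11L, penalty = 2) {
  inp <- .selectionInputs(table)
  fit <- tryCatch(.marsFit(inp$X, inp$y, maxTerms = maxTerms,
                           nKnots = nKnots, penalty = penalty),
                  error = function(e) stop("MARS fit failed: ",
                                           conditionMessage(e)))
  counts <- structure(numeric(ncol(inp$X)), names = colnames(inp$X))
  for (tm in fit$terms)
    counts[fit$featureNames[tm$feature]] <-
      counts[fit$featureNames[tm$feature]] + 1
  sel <- .marsSelected(fit)
  .SelectionResult("mars", scores = counts, selected = sel,
                   settings = list(maxTerms = maxTerms, nKnots = nKnots,
                                   penalty = penalty))
}

#' Run a selection method by name
#'
#' @param table A [FeatureTable].
#' @param method One of `"pearson"`, `"spearman"`, `"pca"`, `"rf"`,
#'   `"gpr_ard"`, `"mars"`.
#' @param ... Passed to the method-specific function.
#' @return A [SelectionResult-class].
#' @export
selectFeatures <- function(table, method = c("pearson", "spearman", "pca",
                                             "rf", "gpr_ard", "mars"), ...) {
  method <- match.arg(method)
  switch(method,
    pearson = correlationSelect(table, "pearson", ...),
    spearman = correlationSelect(table, "spearman", ...),
    pca = pcaReduce(table, ...),
    rf = rfSelect(table, ...),
    gpr_ard = gprArdSelect(table, ...),
    mars = marsSelect(table, ...))
}
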
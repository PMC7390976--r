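## Generics and accessors. Slots are never touched directly by user code.

#' @rdname accessors
#' @export
setGeneric("runId", function(x) standardGeneric("runId"))

#' @rdname accessors
#' @export
setGeneric("runIds", function(x) standardGeneric("runIds"))

#' @rdname accessors
#' @export
setGeneric("cmContent", function(x) standardGeneric("cmContent"))

#' @rdname accessors
#' @export
setGeneric("mediaChanges", function(x) standardGeneric("mediaChanges"))

#' @rdname accessors
#' @export
setGeneric("onlineSeries", function(x, variable) standardGeneric("onlineSeries"))

#' @rdname accessors
#' @export
setGeneric("offlineSamples", function(x) standardGeneric("offlineSamples"))

#' @rdname accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname accessors
#' @export
setGeneric("featureScores", function(x) standardGeneric("featureScores"))

#' Predict CM content and class
#'
#' `predictCm()` returns the regression backend's real-valued prediction of
#' the day-10 cardiomyocyte content, clipped to `[0, 100]` percent.
#' `predictClass()` thresholds that prediction into the binary
#' sufficient/insufficient classes; the direct `rf_classifier` backend votes
#' on the labels instead (probability ties go to the positive,
#' `insufficient`, class). See [trainModel()].
#'
#' @param model A [CmModel-class].
#' @param newdata A [FeatureTable], matrix/data.frame with named columns, or
#'   a single named feature vector; must contain every training feature.
#' @param ... Unused.
#' @return `predictCm()`: numeric percent per run; `predictClass()`: factor
#'   with levels `insufficient`, `sufficient`.
#' @export
setGeneric("predictCm", function(model, newdata, ...) standardGeneric("predictCm"))

#' @rdname predictCm
#' @export
setGeneric("predictClass", function(model, newdata, ...)
  standardGeneric("predictClass"))

#' @rdname accessors
#' @export
setGeneric("cvMetrics", function(x) standardGeneric("cvMetrics"))

## ---------------------------------------------------------------------------
## Accessor methods
## ---------------------------------------------------------------------------

#' Accessors for stirredCM objects
#'
#' @description
#' `runId()` / `runIds()` return run identifiers; `cmContent()` the endpoint
#' cardiomyocyte content (percent); `mediaChanges()` the flagged media-change
#' intervals; `onlineSeries()` one online signal of a run; `offlineSamples()`
#' the per-day offline table; `featureNames()` / `featureValues()` the feature
#' vocabulary and the runs-by-features value matrix of a [FeatureTable];
#' `selectedFeatures()` / `featureScores()` the outcome of a selection method;
#' `cvMetrics()` the aggregate metrics of a [CvResult-class].
#'
#' @param x An object.
#' @param variable For `onlineSeries()`, `"DO"`, `"pH"` or `"DO_per_density"`.
#' @name accessors
#' @aliases runId runIds cmContent mediaChanges onlineSeries offlineSamples
#'   featureNames featureValues selectedFeatures featureScores cvMetrics
#' @return See the description for each accessor.
#' @examples
#' md <- RunMetadata("r1", precultureTime = 48)
#' runId(md)
NULL

#' @rdname accessors
setMethod("runId", "RunMetadata", function(x) x@runId)

#' @rdname accessors
setMethod("runId", "BioreactorRun", function(x) x@metadata@runId)

#' @rdname accessors
setMethod("mediaChanges", "RunMetadata", function(x) x@mediaChanges)

#' @rdname accessors
setMethod("mediaChanges", "BioreactorRun", function(x) x@metadata@mediaChanges)

#' @rdname accessors
setMethod("cmContent", "BioreactorRun", function(x) x@cmContent)

#' @rdname accessors
setMethod("onlineSeries", "BioreactorRun", function(x, variable) {
  for (s in x@online) if (identical(s@variable, variable)) return(s)
  NULL
})

#' @rdname accessors
setMethod("offlineSamples", "BioreactorRun", function(x) x@offline)

#' Run metadata of a run
#' @param run A [BioreactorRun] object.
#' @return The [RunMetadata] object of the run.
#' @export
runMetadata <- function(run) {
  stopifnot(is(run, "BioreactorRun"))
  run@metadata
}

#' Series times and values
#' @param series An [OnlineSeries] object.
#' @return Numeric vector of timestamps (hours) or measurement values.
#' @export
seriesTimes <- function(series) series@times

#' @rdname seriesTimes
#' @export
seriesValues <- function(series) series@values

#' @rdname seriesTimes
#' @export
seriesVariable <- function(series) series@variable

#' @rdname accessors
setMethod("runIds", "FeatureTable", function(x) colnames(x))

#' @rdname accessors
setMethod("runIds", "CvResult", function(x) x@runIds)

#' @rdname accessors
setMethod("featureNames", "FeatureTable", function(x) rownames(x))

#' @rdname accessors
setMethod("featureValues", "FeatureTable", function(x)
  t(SummarizedExperiment::assay(x, "features")))

#' @rdname accessors
setMethod("cmContent", "FeatureTable", function(x) {
  cm <- SummarizedExperiment::colData(x)$cmContent
  names(cm) <- colnames(x)
  cm
})

#' @rdname accessors
setMethod("selectedFeatures", "SelectionResult", function(x) x@selected)

#' @rdname accessors
setMethod("featureScores", "SelectionResult", function(x) x@scores)

#' Selection method and settings
#' @param x A [SelectionResult-class] object.
#' @return The selection method name, or its settings list.
#' @export
selectionMethod <- function(x) x@method

#' @rdname selectionMethod
#' @export
selectionSettings <- function(x) x@settings

#' @rdname selectionMethod
#' @export
selectionDetails <- function(x) x@details

#' Model accessors
#' @param model A [CmModel-class] object.
#' @return Backend name, feature list or classification threshold.
#' @export
modelBackend <- function(model) model@backend

#' @rdname modelBackend
#' @export
modelFeatures <- function(model) model@features

#' @rdname modelBackend
#' @export
modelThreshold <- function(model) model@threshold

#' @rdname accessors
setMethod("cvMetrics", "CvResult", function(x) x@metrics)

#' Per-fold labels and per-trial metrics of a cross-validation result
#' @param x A [CvResult-class] object.
#' @return Factors of actual/predicted labels, the scheme name, or the list of
#'   per-trial metric reports (Monte-Carlo scheme only).
#' @export
cvActual <- function(x) x@actual

#' @rdname cvActual
#' @export
cvPredicted <- function(x) x@predicted

#' @rdname cvActual
#' @export
cvScheme <- function(x) x@scheme

#' @rdname cvActual
#' @export
cvPerTrial <- function(x) x@perTrial

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "RunMetadata", function(object) {
  cat("RunMetadata:", object@runId, "\n")
  cat(sprintf("  preculture %.0f h | IWP2 %.0f h | CHIR %.1f uM | %.0f rpm | %d media change(s)\n",
              object@precultureTime, object@iwp2TreatmentTime,
              object@chirConcentration, object@rotationSpeed,
              nrow(object@mediaChanges)))
})

setMethod("show", "OnlineSeries", function(object) {
  n <- length(object@times)
  cat(sprintf("OnlineSeries '%s': %d samples", object@variable, n))
  if (n) cat(sprintf(" over [%.1f, %.1f] h", object@times[1L], object@times[n]))
  cat("\n")
})

setMethod("show", "BioreactorRun", function(object) {
  cat("BioreactorRun:", runId(object), "\n")
  vars <- vapply(object@online, seriesVariable, character(1))
  cat("  online:", if (length(vars)) paste(vars, collapse = ", ") else "none", "\n")
  cat("  offline samples:", nrow(object@offline), "day(s)\n")
  cm <- object@cmContent
  cat("  endpoint CM content:",
      if (is.na(cm)) "not measured (prediction-only)" else sprintf("%.1f%%", cm),
      "\n")
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d run(s) x %d feature(s), cutoff '%s'\n",
              ncol(object), nrow(object),
              S4Vectors::metadata(object)$cutoff %||% "none"))
  cm <- cmContent(object)
  cat(sprintf("  outcome present for %d/%d run(s)\n", sum(!is.na(cm)), length(cm)))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult (%s): %d feature(s) scored\n",
              object@method, length(object@scores)))
  if (object@method == "pca") {
    cat(sprintf("  %d principal component(s) retained (%.1f%% variance)\n",
                object@details$nComponents,
                100 * sum(object@details$explainedVariance[
                  seq_len(object@details$nComponents)])))
  } else {
    cat(sprintf("  %d feature(s) selected\n", length(object@selected)))
    if (length(object@selected))
      cat("  top:", paste(utils::head(object@selected, 5), collapse = ", "), "\n")
  }
})

setMethod("show", "CmModel", function(object) {
  cat(sprintf("CmModel (%s): %d feature(s), threshold %.0f%% CM content\n",
              object@backend, length(object@features), object@threshold))
})

setMethod("show", "CvResult", function(object) {
  cat(sprintf("CvResult (%s): %d prediction(s)\n", object@scheme,
              length(object@predicted)))
  m <- object@metrics
  if (length(m))
    cat(sprintf("  accuracy %.3f | precision %s | recall %s | MCC %.3f\n",
                m$accuracy, .fmtOrNA(m$precision), .fmtOrNA(m$recall), m$mcc))
  if (length(object@perTrial))
    cat(sprintf("  %d Monte-Carlo trial(s)\n", length(object@perTrial)))
})
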
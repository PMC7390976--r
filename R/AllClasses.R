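#' @import methods
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.ONLINE_VARIABLES <- c("DO", "pH", "DO_per_density")

## Day labels: d0/d1 are the two preculture days (negative time relative to
## differentiation induction), dd0..dd10 the differentiation days.
.DAY_LABELS <- c("d0", "d1", paste0("dd", 0:10))

#' Day window boundaries
#'
#' Maps a day label to its half-open time window in hours relative to
#' differentiation induction (t = 0 at CHIR addition). Preculture days d0 and
#' d1 span [-48, -24) and [-24, 0); differentiation day ddk spans
#' [24k, 24k + 24).
#'
#' @param label A day label, one of `d0`, `d1`, `dd0` ... `dd10`.
#' @return Numeric vector `c(start, end)` in hours.
#' @examples
#' dayWindow("dd0")
#' dayWindow("d1")
#' @export
dayWindow <- function(label) {
  label <- as.character(label)
  stopifnot(length(label) == 1L)
  if (!label %in% .DAY_LABELS)
    stop("unknown day label: ", label)
  if (label == "d0") return(c(-48, -24))
  if (label == "d1") return(c(-24, 0))
  k <- as.integer(sub("^dd", "", label))
  c(24 * k, 24 * k + 24)
}

.dayWindowEnd <- function(label) dayWindow(label)[2L]

## ---------------------------------------------------------------------------
## RunMetadata
## ---------------------------------------------------------------------------

#' @rdname RunMetadata
#' @export
setClass("RunMetadata",
  representation(
    runId = "character",
    precultureTime = "numeric",
    iwp2TreatmentTime = "numeric",
    chirConcentration = "numeric",
    rotationSpeed = "numeric",
    mediaChanges = "matrix"
  )
)

setValidity("RunMetadata", function(object) {
  msg <- character(0)
  if (length(object@runId) != 1L || !nzchar(object@runId))
    msg <- c(msg, "runId must be a single non-empty string")
  if (length(object@precultureTime) != 1L || !is.finite(object@precultureTime) ||
      object@precultureTime <= 0)
    msg <- c(msg, "precultureTime must be a single positive number of hours")
  if (length(object@iwp2TreatmentTime) != 1L ||
      !is.finite(object@iwp2TreatmentTime) || object@iwp2TreatmentTime < 0)
    msg <- c(msg, "iwp2TreatmentTime must be a single non-negative number of hours")
  mc <- object@mediaChanges
  if (ncol(mc) != 2L) {
    msg <- c(msg, "mediaChanges must be a two-column (start, end) matrix")
  } else if (nrow(mc) > 0L) {
    if (any(!is.finite(mc)))
      msg <- c(msg, "mediaChanges must be finite")
    else {
      if (any(mc[, 1L] >= mc[, 2L]))
        msg <- c(msg, "each media-change interval must have start < end")
      if (nrow(mc) > 1L) {
        o <- order(mc[, 1L])
        so <- mc[o, , drop = FALSE]
        if (any(so[-1L, 1L] < so[-nrow(so), 2L]))
          msg <- c(msg, "media-change intervals must be non-overlapping")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Run metadata
#'
#' Scalar process conditions of one bioreactor differentiation run together
#' with the media-change intervals flagged for that run.
#'
#' @param runId Unique run identifier.
#' @param precultureTime Preculture (expansion) duration in hours; must be
#'   positive. Preculture spans negative times relative to induction.
#' @param iwp2TreatmentTime Residence time of the WNT inhibitor IWP2 in hours
#'   (48 h in the standard protocol).
#' @param chirConcentration CHIR99021 concentration in micromolar.
#' @param rotationSpeed Impeller speed in rpm.
#' @param mediaChanges Two-column numeric matrix of (start, end) hours of
#'   media-change intervals, relative to differentiation induction.
#' @return A `RunMetadata` object.
#' @examples
#' RunMetadata("run01", precultureTime = 48, iwp2TreatmentTime = 48)
#' @export
RunMetadata <- function(runId, precultureTime, iwp2TreatmentTime = 48,
                        chirConcentration = 5, rotationSpeed = 60,
                        mediaChanges = matrix(numeric(0), ncol = 2)) {
  mediaChanges <- matrix(as.numeric(mediaChanges), ncol = 2,
                         dimnames = list(NULL, c("start", "end")))
  new("RunMetadata", runId = as.character(runId),
      precultureTime = as.numeric(precultureTime),
      iwp2TreatmentTime = as.numeric(iwp2TreatmentTime),
      chirConcentration = as.numeric(chirConcentration),
      rotationSpeed = as.numeric(rotationSpeed),
      mediaChanges = mediaChanges)
}

## ---------------------------------------------------------------------------
## OnlineSeries
## ---------------------------------------------------------------------------

#' @rdname OnlineSeries
#' @export
setClass("OnlineSeries",
  representation(variable = "character", times = "numeric", values = "numeric")
)

setValidity("OnlineSeries", function(object) {
  msg <- character(0)
  if (length(object@variable) != 1L || !object@variable %in% .ONLINE_VARIABLES)
    msg <- c(msg, paste0("variable must be one of: ",
                         paste(.ONLINE_VARIABLES, collapse = ", ")))
  if (length(object@times) != length(object@values))
    msg <- c(msg, "times and values must have equal length")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, sprintf("series '%s': times must be strictly increasing",
                          object@variable))
  if (any(!is.finite(object@values)))
    msg <- c(msg, sprintf("series '%s': values must be finite", object@variable))
  if (identical(object@variable, "DO") && length(object@values) &&
      (min(object@values) < 0 || max(object@values) > 200))
    msg <- c(msg, "DO values must lie in [0, 200] % air saturation")
  if (identical(object@variable, "pH") && length(object@values) &&
      (min(object@values) < 4 || max(object@values) > 10))
    msg <- c(msg, "pH values must lie in [4, 10]")
  if (length(msg)) msg else TRUE
})

#' Online time series
#'
#' One continuously monitored bioreactor signal: dissolved oxygen (`DO`, in %
#' air saturation), `pH`, or the derived density-normalised oxygen signal
#' (`DO_per_density`). Times are hours relative to differentiation induction;
#' preculture samples have negative times.
#'
#' @param variable `"DO"`, `"pH"` or `"DO_per_density"`.
#' @param times Strictly increasing numeric timestamps in hours.
#' @param values Finite measurements at those times.
#' @return An `OnlineSeries` object.
#' @examples
#' OnlineSeries("DO", times = c(0, 1, 2), values = c(98, 97.5, 96))
#' @export
OnlineSeries <- function(variable, times, values) {
  new("OnlineSeries", variable = as.character(variable),
      times = as.numeric(times), values = as.numeric(values))
}

## ---------------------------------------------------------------------------
## BioreactorRun
## ---------------------------------------------------------------------------

.OFFLINE_COLUMNS <- c("day", "time", "density", "aggregate", "glucose", "lactate")

#' @rdname BioreactorRun
#' @export
setClass("BioreactorRun",
  representation(
    metadata = "RunMetadata",
    online = "list",
    offline = "data.frame",
    cmContent = "numeric"
  )
)

setValidity("BioreactorRun", function(object) {
  msg <- character(0)
  vars <- vapply(object@online, function(s) s@variable, character(1))
  if (!all(vapply(object@online, is, logical(1), "OnlineSeries")))
    msg <- c(msg, "online must be a list of OnlineSeries objects")
  else if (anyDuplicated(vars))
    msg <- c(msg, "at most one online series per variable")
  off <- object@offline
  if (!all(.OFFLINE_COLUMNS %in% names(off))) {
    msg <- c(msg, paste0("offline table must contain columns: ",
                         paste(.OFFLINE_COLUMNS, collapse = ", ")))
  } else if (nrow(off)) {
    if (anyDuplicated(off$day))
      msg <- c(msg, "offline day labels must be unique")
    if (!all(off$day %in% .DAY_LABELS))
      msg <- c(msg, "offline day labels must be valid day labels")
    else {
      win <- t(vapply(off$day, dayWindow, numeric(2)))
      bad <- is.finite(off$time) & (off$time < win[, 1] | off$time >= win[, 2])
      if (any(bad))
        msg <- c(msg, sprintf("offline sample time inconsistent with day label: %s",
                              paste(off$day[bad], collapse = ", ")))
    }
    for (v in c("density", "aggregate")) {
      x <- off[[v]]
      if (any(!is.na(x) & x < 0))
        msg <- c(msg, sprintf("offline %s values must be non-negative", v))
    }
  }
  cm <- object@cmContent
  if (length(cm) != 1L)
    msg <- c(msg, "cmContent must be a single value (NA when not yet measured)")
  else if (!is.na(cm) && (cm < 0 || cm > 100))
    msg <- c(msg, "cmContent must lie in [0, 100] percent")
  if (length(msg)) msg else TRUE
})

#' A bioreactor differentiation run
#'
#' Container for one stirred-tank differentiation experiment: process
#' metadata, online DO/pH series, daily offline samples (viable cell density
#' in 1e6 cells/mL, mean aggregate diameter in micrometres, glucose and
#' lactate in mmol/L) and, when the endpoint flow cytometry has been
#' performed, the day-10 cardiomyocyte content in percent.
#'
#' @param metadata A [RunMetadata] object.
#' @param online List of [OnlineSeries] objects, at most one per variable.
#' @param offline `data.frame` with columns `day`, `time`, `density`,
#'   `aggregate`, `glucose`, `lactate`; missing measurements are `NA`.
#' @param cmContent Endpoint cardiomyocyte content in percent, or `NA` for a
#'   prediction-only run.
#' @return A `BioreactorRun` object.
#' @examples
#' md <- RunMetadata("r1", precultureTime = 48)
#' run <- BioreactorRun(md, online = list(
#'   OnlineSeries("DO", 0:3, c(98, 97, 96, 95))))
#' runId(run)
#' @export
BioreactorRun <- function(metadata, online = list(),
                          offline = emptyOfflineTable(), cmContent = NA_real_) {
  offline <- as.data.frame(offline, stringsAsFactors = FALSE)
  new("BioreactorRun", metadata = metadata, online = online,
      offline = offline, cmContent = as.numeric(cmContent))
}

#' @rdname BioreactorRun
#' @export
emptyOfflineTable <- function() {
  data.frame(day = character(0), time = numeric(0), density = numeric(0),
             aggregate = numeric(0), glucose = numeric(0), lactate = numeric(0),
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## FeatureTable (SummarizedExperiment subclass)
## ---------------------------------------------------------------------------

#' @rdname FeatureTable
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  msg <- character(0)
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "FeatureTable must carry a 'features' assay")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate run ids")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate feature names")
  if (!"cmContent" %in% names(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must carry a cmContent column (NA allowed)")
  cutoff <- S4Vectors::metadata(object)$cutoff
  if (!is.null(cutoff) && !identical(cutoff, "none")) {
    ends <- vapply(rownames(object), .featureWindowEnd, numeric(1))
    if (any(ends > .dayWindowEnd(cutoff), na.rm = TRUE))
      msg <- c(msg, sprintf("table contains features past the %s cutoff", cutoff))
  }
  if (length(msg)) msg else TRUE
})

#' Engineered feature table
#'
#' Runs-by-features matrix of engineered bioprocess features, stored as a
#' [SummarizedExperiment::SummarizedExperiment] with features as rows and runs
#' as columns; the endpoint cardiomyocyte content travels in `colData` so it
#' can never be confused with a predictor.
#'
#' @param values Numeric matrix, runs in rows and features in columns (the
#'   orientation of the delimited on-disk format), or features x runs with
#'   `byRun = FALSE`.
#' @param runIds Run identifiers (defaults to rownames of `values`).
#' @param cmContent Optional endpoint cardiomyocyte content per run (percent).
#' @param cutoff The feature-set cutoff the table was built under
#'   (`"dd7"`, `"dd5"` or `"none"`).
#' @param byRun Whether `values` has runs as rows.
#' @return A `FeatureTable` object.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("r1", "r2"),
#'                             c("do.mean.dd0", "ph.mean.dd1", "meta.iwp2_time")))
#' ft <- FeatureTable(m, cmContent = c(91, 72))
#' featureNames(ft)
#' @export
FeatureTable <- function(values, runIds = NULL, cmContent = NULL,
                         cutoff = "none", byRun = TRUE) {
  values <- as.matrix(values)
  if (byRun) values <- t(values)
  if (!is.null(runIds)) colnames(values) <- runIds
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("run%02d", seq_len(ncol(values)))
  if (is.null(cmContent)) cmContent <- rep(NA_real_, ncol(values))
  cd <- S4Vectors::DataFrame(runId = colnames(values),
                             cmContent = as.numeric(cmContent))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = values), colData = cd)
  S4Vectors::metadata(se)$cutoff <- cutoff
  new("FeatureTable", se)
}

## ---------------------------------------------------------------------------
## SelectionResult
## ---------------------------------------------------------------------------

#' Feature-selection result
#'
#' A selection method's ranked per-feature scores and the subset it selected
#' (for PCA: the retained principal components and their loadings, held in
#' `selectionDetails()`). Created by [selectFeatures()] and the
#' method-specific functions; never constructed by hand.
#'
#' @name SelectionResult
#' @aliases SelectionResult-class
#' @seealso [selectFeatures()], [featureScores()], [selectedFeatures()]
#' @export
setClass("SelectionResult",
  representation(method = "character", scores = "numeric",
                 selected = "character", settings = "list", details = "list")
)

setValidity("SelectionResult", function(object) {
  msg <- character(0)
  methods <- c("pearson", "spearman", "pca", "rf", "gpr_ard", "mars")
  if (length(object@method) != 1L || !object@method %in% methods)
    msg <- c(msg, paste0("method must be one of: ", paste(methods, collapse = ", ")))
  if (any(!is.finite(object@scores)))
    msg <- c(msg, "scores must be finite")
  if (object@method != "pca" &&
      !all(object@selected %in% names(object@scores)))
    msg <- c(msg, "selected features must be a subset of the scored features")
  if (object@method == "pca") {
    evr <- object@details$explainedVariance
    if (!is.null(evr) && (any(evr < 0) || any(evr > 1) || sum(evr) > 1 + 1e-8))
      msg <- c(msg, "explained-variance ratios must lie in [0,1] and sum to <= 1")
  }
  if (length(msg)) msg else TRUE
})

.SelectionResult <- function(method, scores, selected, settings = list(),
                             details = list()) {
  new("SelectionResult", method = method, scores = scores,
      selected = selected, settings = settings, details = details)
}

## ---------------------------------------------------------------------------
## CmModel
## ---------------------------------------------------------------------------

.MODEL_BACKENDS <- c("mars", "rf_regressor", "rf_classifier", "gpr")

#' @rdname trainModel
#' @export
setClass("CmModel",
  representation(backend = "character", fit = "list", features = "character",
                 threshold = "numeric", seed = "numeric", preprocess = "list")
)

setValidity("CmModel", function(object) {
  msg <- character(0)
  if (!object@backend %in% .MODEL_BACKENDS)
    msg <- c(msg, paste0("backend must be one of: ",
                         paste(.MODEL_BACKENDS, collapse = ", ")))
  if (length(object@threshold) != 1L || object@threshold <= 0 ||
      object@threshold >= 100)
    msg <- c(msg, "threshold must lie in (0, 100) percent")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## CvResult
## ---------------------------------------------------------------------------

#' @rdname looCv
#' @export
setClass("CvResult",
  representation(scheme = "character", runIds = "character",
                 actual = "factor", predicted = "factor",
                 metrics = "list", perTrial = "list", seed = "numeric")
)

setValidity("CvResult", function(object) {
  msg <- character(0)
  if (!object@scheme %in% c("loo", "monte_carlo", "holdout"))
    msg <- c(msg, "scheme must be loo, monte_carlo or holdout")
  if (length(object@actual) != length(object@predicted))
    msg <- c(msg, "actual and predicted must have equal length")
  if (length(msg)) msg else TRUE
})

.CvResult <- function(scheme, runIds, actual, predicted, metrics,
                      perTrial = list(), seed = NA_real_) {
  new("CvResult", scheme = scheme, runIds = as.character(runIds),
      actual = actual, predicted = predicted, metrics = metrics,
      perTrial = perTrial, seed = as.numeric(seed))
}
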
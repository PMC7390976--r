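## Finite-difference operators and day-window averaging used by the feature
## engineering stage. The gradient of a signal y sampled at strictly
## increasing times t is the backward difference quotient
##   g_i = (y_i - y_{i-1}) / (t_i - t_{i-1}),
## and the second derivative divides consecutive gradients by the same time
## step,
##   h_i = (g_i - g_{i-1}) / (t_i - t_{i-1}).
## Both are exact for polynomials of the matching degree on any grid
## (gradients for linear signals; for quadratics the second difference is the
## constant curvature on unit-spaced grids).

.checkSeriesArgs <- function(values, times, minPoints) {
  if (length(values) != length(times))
    stop("values and times must have equal length")
  if (length(values) < minPoints)
    stop("need at least ", minPoints, " points")
  d <- diff(times)
  if (any(d == 0)) stop("duplicate timestamps (zero denominator)")
  if (any(d < 0)) stop("times must be strictly increasing")
  invisible(TRUE)
}

#' Gradient series (backward difference quotients)
#'
#' Estimates the instantaneous gradient of a bioreactor signal at each
#' timestamp after the first, as the difference quotient over the preceding
#' interval.
#'
#' @param values Numeric measurements.
#' @param times Strictly increasing timestamps (hours).
#' @return A list with components `time` (timestamps `times[-1]`) and `value`
#'   (the gradients).
#' @examples
#' gradientSeries(c(2, 4), c(0, 1))$value      # 2
#' gradientSeries((0:2)^2, 0:2)$value          # 1, 3
#' @seealso [secondDerivativeSeries()]
#' @export
gradientSeries <- function(values, times) {
  .checkSeriesArgs(values, times, 2L)
  list(time = times[-1L], value = diff(values) / diff(times))
}

#' Second-derivative series
#'
#' Divides consecutive gradients (see [gradientSeries()]) by the local time
#' step, yielding a curvature estimate at each timestamp after the second.
#'
#' @inheritParams gradientSeries
#' @return A list with components `time` (`times[-(1:2)]`) and `value`.
#' @examples
#' secondDerivativeSeries((0:2)^2, 0:2)$value  # 2
#' @export
secondDerivativeSeries <- function(values, times) {
  .checkSeriesArgs(values, times, 3L)
  g <- diff(values) / diff(times)
  tg <- times[-1L]
  list(time = tg[-1L], value = diff(g) / diff(tg))
}

#' Day-window average with media-change exclusion
#'
#' Arithmetic mean of the samples of an online series falling inside a day
#' window, after removing any sample inside a flagged media-change interval
#' (media changes transiently disturb DO and pH and are excluded from the
#' day averages).
#'
#' @param series An [OnlineSeries] object, or a list with `times`/`values`.
#' @param window A day label (`"dd3"`) or a numeric `c(start, end)` window in
#'   hours; the window is half-open `[start, end)`.
#' @param exclusions Two-column matrix of (start, end) intervals to exclude,
#'   typically `mediaChanges(run)`; `NULL` for none.
#' @return The mean, or `NA` when no sample survives (missing is a value, not
#'   an error).
#' @examples
#' s <- OnlineSeries("DO", times = c(1, 2, 3, 4), values = c(10, 10, 50, 10))
#' dayAverage(s, c(0, 24), exclusions = cbind(2.5, 3.5))  # 10
#' @export
dayAverage <- function(series, window, exclusions = NULL) {
  if (is(series, "OnlineSeries")) {
    times <- series@times; values <- series@values
  } else {
    times <- series$times %||% series$time
    values <- series$values %||% series$value
  }
  if (is.character(window)) window <- dayWindow(window)
  keep <- times >= window[1L] & times < window[2L] &
    !.inExclusion(times, exclusions) & !is.na(values)
  if (!any(keep)) return(NA_real_)
  mean(values[keep])
}

#' Cell-density-normalised dissolved oxygen
#'
#' Divides every DO sample of a run by the viable cell density at that time,
#' obtained by linear interpolation between the run's offline density
#' samples; timestamps outside the offline density span use the nearest
#' sample (flagged with a message). Units: \% air saturation per 1e6
#' cells/mL. The resulting signal tracks per-cell oxygen demand rather than
#' culture-level depletion.
#'
#' @param run A [BioreactorRun] with a DO series and at least two offline
#'   density measurements.
#' @return An [OnlineSeries] with variable `"DO_per_density"`.
#' @export
densityNormalizedDO <- function(run) {
  do <- onlineSeries(run, "DO")
  if (is.null(do)) stop("run has no DO series")
  off <- offlineSamples(run)
  ok <- !is.na(off$density) & !is.na(off$time)
  if (sum(ok) < 2L)
    stop("need at least two offline cell-density values to normalise DO")
  ot <- off$time[ok]; ov <- off$density[ok]
  o <- order(ot); ot <- ot[o]; ov <- ov[o]
  t <- seriesTimes(do)
  if (any(t < min(ot)) || any(t > max(ot)))
    message("densityNormalizedDO: timestamps outside the offline density span; ",
            "using nearest-sample extrapolation")
  dens <- .interpNearest(ot, ov, t)
  if (any(dens <= 0)) stop("interpolated cell density <= 0")
  OnlineSeries("DO_per_density", times = t, values = seriesValues(do) / dens)
}
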
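## Feature grammar
## ---------------
## Every engineered feature has a canonical machine name
##   <variable>.<statistic>.<window>
## with variables
##   do       dissolved oxygen (% air saturation), online
##   ph       culture pH, online
##   dopd     cell-density-normalised DO (% per 1e6 cells/mL), derived online
##   density  viable cell density (1e6 cells/mL), offline daily
##   aggsize  mean aggregate diameter (um), offline daily
##   glucose / lactate (mmol/L), offline daily
##   meta     scalar process conditions
## and statistics
##   mean     day-window average of the signal (media changes excluded)
##   grad     day-window average of the instantaneous gradient series
##   accel    day-window average of the second-derivative series
##   value    the offline measurement of that day
##   grad with a day-pair window ("dd0_dd1") or "overall": day-to-day or
##            first-to-last difference quotient, per day
## Windows are day labels (d0/d1 preculture, dd0..dd10 differentiation).
## The human-readable names printed in the published feature listings are
## registered aliases of canonical names (see resolveFeatureName).

.ONLINE_FEATURE_VARS <- c("do", "ph", "dopd")
.OFFLINE_FEATURE_VARS <- c("density", "aggsize", "glucose", "lactate")
.META_FEATURES <- c("meta.preculture_time", "meta.iwp2_time",
                    "meta.chir_concentration", "meta.rotation_speed")

#' Parse a canonical feature name
#'
#' @param name A canonical feature name such as `"do.grad.dd2"`,
#'   `"density.grad.dd0_dd1"` or `"meta.iwp2_time"`.
#' @return A list with `variable`, `statistic` and `window`, or `NULL` when
#'   the name is not part of the grammar.
#' @examples
#' parseFeatureName("dopd.accel.dd3")
#' @export
parseFeatureName <- function(name) {
  if (name %in% .META_FEATURES)
    return(list(variable = "meta", statistic = "value",
                window = sub("^meta\\.", "", name)))
  parts <- strsplit(name, ".", fixed = TRUE)[[1L]]
  if (length(parts) != 3L) return(NULL)
  var <- parts[1L]; stat <- parts[2L]; win <- parts[3L]
  if (var %in% .ONLINE_FEATURE_VARS) {
    if (!stat %in% c("mean", "grad", "accel")) return(NULL)
    days <- if (var == "dopd") paste0("dd", 0:10) else .DAY_LABELS
    if (!win %in% days) return(NULL)
    return(list(variable = var, statistic = stat, window = win))
  }
  if (var %in% .OFFLINE_FEATURE_VARS) {
    if (stat == "value") {
      if (!win %in% paste0("dd", 0:10)) return(NULL)
      return(list(variable = var, statistic = stat, window = win))
    }
    if (stat == "grad") {
      if (win == "overall")
        return(list(variable = var, statistic = stat, window = win))
      pair <- strsplit(win, "_", fixed = TRUE)[[1L]]
      if (length(pair) == 2L && all(pair %in% paste0("dd", 0:10)) &&
          .ddIndex(pair[1L]) < .ddIndex(pair[2L]))
        return(list(variable = var, statistic = stat, window = win))
      return(NULL)
    }
    return(NULL)
  }
  NULL
}

.ddIndex <- function(label) as.integer(sub("^dd", "", label))

## End (hours) of the window a feature draws data from; -Inf for features that
## are always available (metadata scalars) or cutoff-aware ("overall").
.featureWindowEnd <- function(name) {
  p <- parseFeatureName(name)
  if (is.null(p)) return(NA_real_)
  if (p$variable == "meta" || p$window == "overall") return(-Inf)
  win <- p$window
  if (grepl("_", win, fixed = TRUE))
    win <- strsplit(win, "_", fixed = TRUE)[[1L]][2L]
  .dayWindowEnd(win)
}

## ---------------------------------------------------------------------------
## Printed-name aliases
## ---------------------------------------------------------------------------

.aliasRegistry <- local({
  reg <- NULL
  function() {
    if (!is.null(reg)) return(reg)
    a <- character(0)
    for (d in .DAY_LABELS) {
      a[sprintf("Average DO concentration %s", d)] <- sprintf("do.mean.%s", d)
      a[sprintf("Average DO concentration gradient %s", d)] <- sprintf("do.grad.%s", d)
      a[sprintf("%s average acceleration of DO gradient", d)] <- sprintf("do.accel.%s", d)
      a[sprintf("%s average pH", d)] <- sprintf("ph.mean.%s", d)
      a[sprintf("%s average pH gradient", d)] <- sprintf("ph.grad.%s", d)
      a[sprintf("%s average acceleration of pH gradient", d)] <- sprintf("ph.accel.%s", d)
    }
    for (d in paste0("dd", 0:10)) {
      a[sprintf("Cell density normalized DO concentration %s", d)] <-
        sprintf("dopd.mean.%s", d)
      a[sprintf("Average cell density normalized DO concentration gradient %s", d)] <-
        sprintf("dopd.grad.%s", d)
      a[sprintf("%s average acceleration of cell density normalized DO gradient", d)] <-
        sprintf("dopd.accel.%s", d)
      a[sprintf("%s cell density", d)] <- sprintf("density.value.%s", d)
      a[sprintf("%s aggregate size", d)] <- sprintf("aggsize.value.%s", d)
      a[sprintf("%s glucose concentration", d)] <- sprintf("glucose.value.%s", d)
      a[sprintf("%s lactate concentration", d)] <- sprintf("lactate.value.%s", d)
    }
    pairs <- utils::combn(paste0("dd", 0:10), 2L)
    for (k in seq_len(ncol(pairs))) {
      di <- pairs[1L, k]; dj <- pairs[2L, k]
      a[sprintf("%s-%s cell density gradient", di, dj)] <-
        sprintf("density.grad.%s_%s", di, dj)
      a[sprintf("%s-%s aggregate size gradient", di, dj)] <-
        sprintf("aggsize.grad.%s_%s", di, dj)
    }
    a["Overall density gradient"] <- "density.grad.overall"
    a["Overall aggregate size gradient"] <- "aggsize.grad.overall"
    a["IWP2 treatment time [h]"] <- "meta.iwp2_time"
    a["Preculture time [h]"] <- "meta.preculture_time"
    a["CHIR concentration [uM]"] <- "meta.chir_concentration"
    a["Rotation speed [rpm]"] <- "meta.rotation_speed"
    reg <<- a
    reg
  }
})

#' Resolve a feature name to its canonical form
#'
#' Accepts either a canonical grammar name or one of the registered
#' human-readable aliases (the names used in the published feature listings,
#' e.g. `"dd0-dd1 cell density gradient"`). Dashes are normalised so en-dash
#' variants of the day-pair names also resolve.
#'
#' @param name Feature name or alias (vectorised).
#' @return Character vector of canonical names; `NA` (with a warning) for
#'   names outside both the grammar and the alias registry.
#' @examples
#' resolveFeatureName("Average DO concentration gradient dd6")
#' resolveFeatureName("IWP2 treatment time [h]")
#' @export
resolveFeatureName <- function(name) {
  reg <- .aliasRegistry()
  out <- vapply(name, function(nm) {
    if (!is.null(parseFeatureName(nm))) return(nm)
    key <- gsub("–|—", "-", trimws(nm))
    key <- gsub("[ ]+", " ", key)
    if (key %in% names(reg)) return(unname(reg[key]))
    NA_character_
  }, character(1))
  if (anyNA(out))
    warning("unrecognised feature name(s): ",
            paste(name[is.na(out)], collapse = ", "))
  unname(out)
}

## ---------------------------------------------------------------------------
## Default schema
## ---------------------------------------------------------------------------

#' Default engineered-feature schema
#'
#' The default pool of 101 candidate bioprocess features: per-day means and
#' mean gradients of DO and pH across the two preculture and first eight
#' differentiation days, second derivatives for the mesoderm-priming window
#' (dd2-dd3), day means/gradients of density-normalised DO across dd0-dd7
#' with second derivatives through dd5, offline cell density, aggregate size,
#' glucose and lactate values on the six sampling days (dd0-dd3, dd5, dd7)
#' with the day-pair and overall gradients of density and aggregate size, and
#' the four scalar process conditions. Membership is configurable: any vector
#' of grammar names is a valid schema.
#'
#' @return Character vector of 101 canonical feature names.
#' @examples
#' length(defaultFeatureSchema())
#' @export
defaultFeatureSchema <- function() {
  online10 <- c("d0", "d1", paste0("dd", 0:7))
  dd8 <- paste0("dd", 0:7)
  offdays <- c("dd0", "dd1", "dd2", "dd3", "dd5", "dd7")
  c(
    sprintf("do.mean.%s", online10),
    sprintf("do.grad.%s", online10),
    sprintf("do.accel.%s", c("dd2", "dd3")),
    sprintf("ph.mean.%s", online10),
    sprintf("ph.grad.%s", online10),
    sprintf("ph.accel.%s", c("dd2", "dd3")),
    sprintf("dopd.mean.%s", dd8),
    sprintf("dopd.grad.%s", dd8),
    sprintf("dopd.accel.%s", paste0("dd", 0:5)),
    sprintf("density.value.%s", offdays),
    c("density.grad.dd0_dd1", "density.grad.dd3_dd5", "density.grad.dd5_dd7",
      "density.grad.overall"),
    sprintf("aggsize.value.%s", offdays),
    c("aggsize.grad.dd2_dd3", "aggsize.grad.dd5_dd7", "aggsize.grad.overall"),
    sprintf("glucose.value.%s", offdays),
    sprintf("lactate.value.%s", offdays),
    .META_FEATURES
  )
}

## ---------------------------------------------------------------------------
## Extraction
## ---------------------------------------------------------------------------

## Restrict a run to measurements taken before tmax, so that a feature-set
## table never consumes data past its cutoff day -- including through the
## density interpolation inside the normalised-DO signal.
.truncateRun <- function(run, tmax) {
  if (!is.finite(tmax)) return(run)
  online <- lapply(run@online, function(s) {
    keep <- seriesTimes(s) < tmax
    OnlineSeries(seriesVariable(s), seriesTimes(s)[keep],
                 seriesValues(s)[keep])
  })
  off <- offlineSamples(run)
  BioreactorRun(runMetadata(run), online = online,
                offline = off[off$time < tmax, , drop = FALSE],
                cmContent = cmContent(run))
}

## Per-run context: exclusion-filtered online signals and their gradient /
## second-derivative series, computed once and reused across features.
.runFeatureContext <- function(run) {
  excl <- mediaChanges(run)
  ctx <- list(offline = offlineSamples(run), metadata = runMetadata(run))
  for (var in c("do", "ph", "dopd")) {
    s <- switch(var,
      do = onlineSeries(run, "DO"),
      ph = onlineSeries(run, "pH"),
      dopd = tryCatch(suppressMessages(densityNormalizedDO(run)),
                      error = function(e) NULL))
    if (is.null(s) || length(seriesTimes(s)) == 0L) next
    keep <- !.inExclusion(seriesTimes(s), excl)
    t <- seriesTimes(s)[keep]; v <- seriesValues(s)[keep]
    entry <- list(time = t, value = v)
    if (length(t) >= 2L) entry$grad <- gradientSeries(v, t)
    if (length(t) >= 3L) entry$accel <- secondDerivativeSeries(v, t)
    ctx[[var]] <- entry
  }
  ctx
}

.windowMean <- function(series, window) {
  if (is.null(series)) return(NA_real_)
  keep <- series$time >= window[1L] & series$time < window[2L]
  if (!any(keep)) return(NA_real_)
  mean(series$value[keep])
}

.offlineValue <- function(off, column, day) {
  i <- match(day, off$day)
  if (is.na(i)) return(NA_real_)
  off[[column]][i]
}

.offlineColumn <- function(var) {
  switch(var, density = "density", aggsize = "aggregate",
         glucose = "glucose", lactate = "lactate")
}

.extractOne <- function(p, ctx, cutoffDay) {
  if (p$variable == "meta") {
    md <- ctx$metadata
    return(switch(p$window,
      preculture_time = md@precultureTime,
      iwp2_time = md@iwp2TreatmentTime,
      chir_concentration = md@chirConcentration,
      rotation_speed = md@rotationSpeed))
  }
  if (p$variable %in% .ONLINE_FEATURE_VARS) {
    entry <- ctx[[p$variable]]
    if (is.null(entry)) return(NA_real_)
    win <- dayWindow(p$window)
    return(switch(p$statistic,
      mean = .windowMean(entry, win),
      grad = .windowMean(entry$grad, win),
      accel = .windowMean(entry$accel, win)))
  }
  col <- .offlineColumn(p$variable)
  off <- ctx$offline
  if (p$statistic == "value")
    return(.offlineValue(off, col, p$window))
  if (p$window == "overall") {
    ok <- !is.na(off[[col]]) & grepl("^dd", off$day)
    days <- .ddIndex(off$day[ok])
    if (!is.na(cutoffDay)) { keep <- days <= cutoffDay
                             days <- days[keep]; ok <- which(ok)[keep] }
    else ok <- which(ok)
    if (length(days) < 2L) return(NA_real_)
    o <- order(days)
    v <- off[[col]][ok][o]; d <- days[o]
    return((v[length(v)] - v[1L]) / (d[length(d)] - d[1L]))
  }
  pair <- strsplit(p$window, "_", fixed = TRUE)[[1L]]
  v1 <- .offlineValue(off, col, pair[1L])
  v2 <- .offlineValue(off, col, pair[2L])
  (v2 - v1) / (.ddIndex(pair[2L]) - .ddIndex(pair[1L]))
}

#' Extract engineered features from a run
#'
#' Computes the requested engineered features for one [BioreactorRun]:
#' day-window means, mean gradients and mean second derivatives of the online
#' signals (media-change samples removed first), per-day offline values,
#' day-pair and overall difference quotients (per day) of the offline
#' variables, and the scalar metadata. Features that cannot be computed from
#' the available data are returned as `NA` with a warning.
#'
#' @param run A [BioreactorRun].
#' @param schema Character vector of canonical feature names (default
#'   [defaultFeatureSchema()]).
#' @param cutoff `"none"`, `"dd7"` or `"dd5"`; measurements at or after the
#'   end of the cutoff day are discarded before extraction (including the
#'   offline densities feeding the DO normalisation), so a feature-set table
#'   never touches data past its cutoff day and `"overall"` gradients are
#'   cutoff-aware.
#' @return Named numeric vector, one value per schema entry.
#' @export
extractFeatures <- function(run, schema = defaultFeatureSchema(),
                            cutoff = c("none", "dd7", "dd5")) {
  cutoff <- match.arg(cutoff)
  cutoffDay <- if (cutoff == "none") NA_integer_ else .ddIndex(cutoff)
  run <- .truncateRun(run, if (cutoff == "none") Inf
                           else .dayWindowEnd(cutoff))
  parsed <- lapply(schema, parseFeatureName)
  bad <- vapply(parsed, is.null, logical(1))
  if (any(bad))
    stop("invalid feature name(s) in schema: ",
         paste(schema[bad], collapse = ", "))
  ctx <- .runFeatureContext(run)
  out <- vapply(parsed, .extractOne, numeric(1), ctx = ctx,
                cutoffDay = cutoffDay)
  names(out) <- schema
  if (anyNA(out))
    warning(sprintf("run %s: %d feature(s) not computable from available data",
                    runId(run), sum(is.na(out))))
  out
}

#' Assemble a cohort feature table
#'
#' Applies [extractFeatures()] to every run and restricts the schema to the
#' requested feature-set cutoff: Feature Set 1 keeps features whose window
#' ends by differentiation day 7, Feature Set 2 by day 5. `"overall"`
#' gradients are recomputed within the cutoff, so a Feature Set 2 table never
#' consumes measurements taken after dd5.
#'
#' @param runs List of [BioreactorRun] objects.
#' @param cutoff `"dd7"` (Feature Set 1), `"dd5"` (Feature Set 2) or
#'   `"none"` (the full candidate pool).
#' @param schema Candidate schema before cutoff filtering.
#' @return A [FeatureTable] whose `colData` carries the endpoint CM content.
#' @examples
#' \donttest{
#' cohort <- generateCohort(syntheticConfig(nRuns = 4, seed = 1))
#' ft <- buildFeatureTable(cohort$runs, cutoff = "dd5")
#' }
#' @export
buildFeatureTable <- function(runs, cutoff = c("dd7", "dd5", "none"),
                              schema = defaultFeatureSchema()) {
  cutoff <- match.arg(cutoff)
  if (length(runs) < 1L) stop("need at least one run")
  isDefault <- identical(schema, defaultFeatureSchema())
  if (cutoff != "none") {
    ends <- vapply(schema, .featureWindowEnd, numeric(1))
    schema <- schema[ends <= .dayWindowEnd(cutoff)]
  }
  vals <- vapply(runs, function(r)
    suppressWarnings(extractFeatures(r, schema, cutoff)), numeric(length(schema)))
  vals <- matrix(vals, nrow = length(schema),
                 dimnames = list(schema, vapply(runs, runId, character(1))))
  nMissing <- sum(is.na(vals))
  if (nMissing > 0L)
    warning(nMissing, " missing feature value(s) in the assembled table")
  if (isDefault && cutoff == "none" && nrow(vals) != 101L)
    warning("default schema produced ", nrow(vals),
            " features (expected 101)")
  cm <- vapply(runs, cmContent, numeric(1))
  FeatureTable(vals, cmContent = cm, cutoff = cutoff, byRun = FALSE)
}
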
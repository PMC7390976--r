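## Plain-text persistence: one YAML manifest per run plus delimited
## time-series files. No binary formats; fixtures stay diffable.

#' Write a run to disk
#'
#' Emits `<out_dir>/<runId>/manifest.yaml` together with one CSV per online
#' variable (`time,value`) and one offline table
#' (`day,time,density,aggregate,glucose,lactate`). [readRun()] inverts the
#' writer exactly (strings and integers exactly, reals at 10 significant
#' digits).
#'
#' @param run A [BioreactorRun].
#' @param outDir Writable output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
writeRun <- function(run, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  runDir <- file.path(outDir, runId(run))
  dir.create(runDir, showWarnings = FALSE)
  md <- runMetadata(run)
  seriesFiles <- list()
  for (s in run@online) {
    f <- sprintf("online_%s.csv", seriesVariable(s))
    utils::write.csv(
      data.frame(time = seriesTimes(s), value = seriesValues(s)),
      file.path(runDir, f), row.names = FALSE)
    seriesFiles[[seriesVariable(s)]] <- f
  }
  offFile <- "offline.csv"
  utils::write.csv(offlineSamples(run), file.path(runDir, offFile),
                   row.names = FALSE)
  mc <- mediaChanges(md)
  manifest <- list(
    run_id = runId(run),
    metadata = list(
      preculture_time = md@precultureTime,
      iwp2_treatment_time = md@iwp2TreatmentTime,
      chir_concentration = md@chirConcentration,
      rotation_speed = md@rotationSpeed),
    media_changes = if (nrow(mc)) unname(apply(mc, 1L, as.list, simplify = FALSE))
                    else list(),
    online_series = seriesFiles,
    offline_table = offFile,
    endpoint_cm_content = if (is.na(cmContent(run))) NULL else cmContent(run))
  path <- file.path(runDir, "manifest.yaml")
  yaml::write_yaml(manifest, path, precision = 10L)
  invisible(path)
}

.manifestField <- function(m, field) {
  v <- m[[field]]
  if (is.null(v))
    stop("malformed manifest: missing field '", field, "'")
  v
}

#' Read a run from its manifest
#'
#' @param manifestPath Path to a `manifest.yaml` written by [writeRun()].
#' @return A validated [BioreactorRun]; runs whose manifest lacks
#'   `endpoint_cm_content` come back with `cmContent()` of `NA`
#'   (prediction-only).
#' @export
readRun <- function(manifestPath) {
  if (!file.exists(manifestPath)) stop("manifest not found: ", manifestPath)
  m <- yaml::read_yaml(manifestPath)
  runDir <- dirname(manifestPath)
  id <- .manifestField(m, "run_id")
  meta <- .manifestField(m, "metadata")
  for (f in c("preculture_time", "iwp2_treatment_time")) .manifestField(meta, f)
  mc <- m$media_changes %||% list()
  mcMat <- if (length(mc))
    do.call(rbind, lapply(mc, function(x) c(x[[1L]], x[[2L]])))
  else matrix(numeric(0), ncol = 2)
  md <- RunMetadata(id,
    precultureTime = meta$preculture_time,
    iwp2TreatmentTime = meta$iwp2_treatment_time,
    chirConcentration = meta$chir_concentration %||% NA_real_,
    rotationSpeed = meta$rotation_speed %||% NA_real_,
    mediaChanges = mcMat)
  online <- list()
  for (var in names(m$online_series %||% list())) {
    f <- file.path(runDir, m$online_series[[var]])
    if (!file.exists(f)) stop("series file missing: ", f)
    d <- utils::read.csv(f)
    online[[length(online) + 1L]] <- tryCatch(
      OnlineSeries(var, d$time, d$value),
      error = function(e)
        stop("invalid series '", var, "': ", conditionMessage(e)))
  }
  off <- utils::read.csv(file.path(runDir, .manifestField(m, "offline_table")),
                         colClasses = c(day = "character"))
  BioreactorRun(md, online = online, offline = off,
                cmContent = m$endpoint_cm_content %||% NA_real_)
}

#' Write / read a feature table as delimited text
#'
#' One header row of canonical feature names, one row per run; the run id is
#' the first column and the endpoint CM content (when present) the last,
#' named `cm_content`. Missing values are written as the literal `NA`
#' sentinel. Reading a file whose header contains a name outside the feature
#' grammar warns and keeps the column verbatim.
#'
#' @param table A [FeatureTable].
#' @param path Output/input CSV path.
#' @return `readFeatureTable()` returns a [FeatureTable];
#'   `writeFeatureTable()` returns `path` invisibly.
#' @export
writeFeatureTable <- function(table, path) {
  vals <- featureValues(table)
  df <- data.frame(run_id = rownames(vals), vals, check.names = FALSE)
  cm <- cmContent(table)
  if (any(!is.na(cm))) df$cm_content <- as.numeric(cm)
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(run_id = "character"))
  if (anyDuplicated(df$run_id))
    stop("duplicate run_id rows in ", path)
  runIds <- df$run_id
  cm <- if ("cm_content" %in% names(df)) df$cm_content else NULL
  featCols <- setdiff(names(df), c("run_id", "cm_content"))
  unknown <- featCols[vapply(featCols,
                             function(f) is.null(parseFeatureName(f)), logical(1))]
  if (length(unknown))
    warning("unknown feature name(s) retained verbatim: ",
            paste(unknown, collapse = ", "))
  vals <- as.matrix(df[, featCols, drop = FALSE])
  rownames(vals) <- runIds
  FeatureTable(vals, cmContent = cm, byRun = TRUE)
}
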
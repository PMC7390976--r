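## End-to-end orchestration: synthetic cohort (or run directory) ->
## feature table(s) -> selection -> model -> cross-validated reports,
## driven by a YAML/JSON config and fully deterministic given config + seed.

.readPipelineConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

.pipelineDefaults <- function() list(
  featureSet = "fs1",
  selection = "rf",
  model = "rf_classifier",
  cv = "loo",
  threshold = 90,
  seed = 1L,
  split = list(train = 42L, test = 16L),
  mc = list(testSize = 5L, trials = 40L)
)

.featureSetCutoff <- function(fs) {
  switch(tolower(fs), fs1 = "dd7", fs2 = "dd5", full = "none",
         stop("config error: featureSet must be fs1, fs2 or full"))
}

#' Run the full prediction pipeline
#'
#' Generates (or loads) a cohort, builds the feature table at the configured
#' feature-set cutoff, optionally splits into training/test runs, performs
#' feature selection, trains the configured model and evaluates it under the
#' configured cross-validation scheme(s). All artifacts (feature table,
#' selection JSON, evaluation reports, log) are written to `outDir` as plain
#' text; identical config + seed reproduces them byte for byte.
#'
#' @param config Path to a YAML/JSON config, or an equivalent named list.
#'   Recognised fields: `data` (either `synthetic` with [syntheticConfig()]
#'   arguments, or `runsDir` with run manifests), `featureSet`
#'   (`fs1`/`fs2`/`full`), `featureWhitelist` (optional canonical names),
#'   `selection` (method name or `"none"`), `model`, `cv` (one or more of
#'   `loo`, `mc`, `holdout`), `split` (`train`/`test` sizes for holdout),
#'   `mc` (`testSize`, `trials`), `threshold`, `seed`.
#' @param outDir Output directory; `NULL` skips writing.
#' @return Invisibly, a list with the feature table(s), selection result,
#'   trained model and one [CvResult-class] per scheme.
#' @export
runPipeline <- function(config, outDir = NULL) {
  cfg <- utils::modifyList(.pipelineDefaults(), .readPipelineConfig(config))
  seed <- as.integer(cfg$seed)
  cutoff <- .featureSetCutoff(cfg$featureSet)

  ## -- data ---------------------------------------------------------------
  if (!is.null(cfg$data$runsDir)) {
    manifests <- list.files(cfg$data$runsDir, pattern = "^manifest\\.yaml$",
                            recursive = TRUE, full.names = TRUE)
    if (!length(manifests)) stop("no run manifests under ", cfg$data$runsDir)
    runs <- lapply(manifests, readRun)
  } else {
    synArgs <- cfg$data$synthetic %||% list()
    if (is.null(synArgs$seed)) synArgs$seed <- seed
    syn <- do.call(syntheticConfig, synArgs)
    runs <- generateCohort(syn)$runs
  }

  ## -- features -----------------------------------------------------------
  table <- buildFeatureTable(runs, cutoff = cutoff)
  if (!is.null(cfg$featureWhitelist)) {
    wl <- resolveFeatureName(cfg$featureWhitelist)
    ends <- vapply(wl, .featureWindowEnd, numeric(1))
    if (cutoff != "none" && any(ends > .dayWindowEnd(cutoff)))
      stop("config error: featureWhitelist contains feature(s) past the ",
           cfg$featureSet, " cutoff: ",
           paste(cfg$featureWhitelist[ends > .dayWindowEnd(cutoff)],
                 collapse = ", "))
    table <- table[wl, ]
  }

  ## -- split --------------------------------------------------------------
  schemes <- cfg$cv
  testTable <- NULL
  if ("holdout" %in% schemes) {
    nTrain <- cfg$split$train
    nTest <- cfg$split$test %||% (ncol(table) - nTrain)
    if (nTrain + nTest > ncol(table))
      stop("config error: split sizes exceed the cohort size")
    idx <- .withSeed(.childSeed(seed, 7L), sample.int(ncol(table)))
    testTable <- table[, idx[nTrain + seq_len(nTest)]]
    table <- table[, idx[seq_len(nTrain)]]
  }

  ## -- selection ----------------------------------------------------------
  selResult <- NULL
  features <- NULL
  if (!identical(cfg$selection, "none")) {
    extra <- if (cfg$selection %in% c("rf", "gpr_ard"))
      list(seed = .childSeed(seed, 2L)) else list()
    selResult <- do.call(selectFeatures,
                         c(list(table = table, method = cfg$selection), extra))
    features <- if (cfg$selection == "pca") selResult
                else selectedFeatures(selResult)
  }

  ## -- model + evaluation -------------------------------------------------
  results <- list()
  for (scheme in schemes) {
    results[[scheme]] <- switch(scheme,
      loo = looCv(table, cfg$model, features = features,
                  threshold = cfg$threshold, seed = .childSeed(seed, 3L)),
      mc = mcCv(table, cfg$model, features = features,
                testSize = cfg$mc$testSize, trials = cfg$mc$trials,
                threshold = cfg$threshold, seed = .childSeed(seed, 4L)),
      holdout = holdoutEvaluate(table, testTable, cfg$model,
                                features = features,
                                threshold = cfg$threshold,
                                seed = .childSeed(seed, 5L)),
      stop("config error: unknown cv scheme '", scheme, "'"))
  }
  model <- if (!is.null(features) && is(features, "SelectionResult"))
    NULL  # PC-space model is fold-local; no single feature-space model
  else trainModel(table, cfg$model, features = features,
                  threshold = cfg$threshold, seed = .childSeed(seed, 6L))

  bundle <- list(config = cfg, featureTable = table, testTable = testTable,
                 selection = selResult, model = model, results = results)

  ## -- artifacts ----------------------------------------------------------
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeFeatureTable(table, file.path(outDir, "feature_table.csv"))
    if (!is.null(testTable))
      writeFeatureTable(testTable, file.path(outDir, "feature_table_test.csv"))
    if (!is.null(selResult))
      writeSelectionResult(selResult,
                           file.path(outDir,
                                     sprintf("selection_%s.json", cfg$selection)))
    for (scheme in names(results))
      writeEvaluationReport(results[[scheme]],
                            file.path(outDir, sprintf("report_%s.json", scheme)))
    cfgFile <- tempfile(fileext = ".json")
    jsonlite::write_json(cfg, cfgFile, auto_unbox = TRUE, force = TRUE)
    writeLines(c(
      sprintf("seed: %d", seed),
      sprintf("config_md5: %s", unname(tools::md5sum(cfgFile))),
      sprintf("runs: %d", length(runs)),
      sprintf("feature_set: %s (cutoff %s)", cfg$featureSet, cutoff),
      sprintf("features_after_cutoff: %d", nrow(table)),
      sprintf("features_selected: %s",
              if (is.null(selResult)) "all"
              else length(selectedFeatures(selResult))),
      sprintf("package_version: %s",
              as.character(utils::packageVersion("stirredCM")))),
      file.path(outDir, "log.txt"))
    unlink(cfgFile)
  }
  invisible(bundle)
}

#' Serialise a selection result or evaluation report as JSON
#'
#' @param x A [SelectionResult-class] or [CvResult-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSelectionResult <- function(x, path) {
  stopifnot(is(x, "SelectionResult"))
  jsonlite::write_json(list(
    method = selectionMethod(x),
    settings = selectionSettings(x),
    scores = as.list(featureScores(x)),
    selected = selectedFeatures(x)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeSelectionResult
#' @export
writeEvaluationReport <- function(x, path) {
  stopifnot(is(x, "CvResult"))
  m <- cvMetrics(x)
  out <- list(
    scheme = cvScheme(x),
    seed = x@seed,
    counts = as.list(m$counts),
    metrics = list(accuracy = m$accuracy, precision = m$precision,
                   recall = m$recall, mcc = m$mcc),
    runs = runIds(x),
    actual = as.character(cvActual(x)),
    predicted = as.character(cvPredicted(x)))
  if (length(cvPerTrial(x)))
    out$perTrial <- lapply(cvPerTrial(x), function(tr)
      list(counts = as.list(tr$counts), accuracy = tr$accuracy,
           precision = tr$precision, recall = tr$recall, mcc = tr$mcc))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
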
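# Fixtures are built in code; nothing is read from disk.

# A hand-constructed run with analytically known feature values:
#   DO(t) = 100 - 0.25 t, pH(t) = 7 + 0.001 t (linear => constant gradients,
#   zero second derivatives), offline densities/aggregates on the default
#   sampling days.
makeManualRun <- function(cm = 85, withEndpoint = TRUE) {
  t <- seq(-48, 191.5, by = 0.5)
  md <- RunMetadata("manual01", precultureTime = 48, iwp2TreatmentTime = 48,
                    chirConcentration = 5, rotationSpeed = 60,
                    mediaChanges = cbind(start = c(30, 78), end = c(31.5, 79.5)))
  offline <- data.frame(
    day = c("dd0", "dd1", "dd2", "dd3", "dd5", "dd7"),
    time = 24 * c(0, 1, 2, 3, 5, 7) + 6,
    density = c(0.5, 1.4, 1.8, 2.0, 2.15, 2.5),
    aggregate = c(100, 130, 155, 175, 210, 240),
    glucose = c(25, 20, 16, 24, 18, 17),
    lactate = c(0.5, 3, 6, 2, 5, 6),
    stringsAsFactors = FALSE)
  BioreactorRun(md,
    online = list(OnlineSeries("DO", t, 100 - 0.25 * t),
                  OnlineSeries("pH", t, 7 + 0.001 * t)),
    offline = offline,
    cmContent = if (withEndpoint) cm else NA_real_)
}

# Small planted cohort feature table + ground truth; coarse sampling keeps
# unit tests fast.
makeCohortTable <- function(n = 20, seed = 1, cutoff = "none", ...) {
  cfg <- syntheticConfig(nRuns = n, seed = seed, samplingInterval = 0.5, ...)
  ch <- generateCohort(cfg)
  ft <- suppressWarnings(buildFeatureTable(ch$runs, cutoff = cutoff))
  list(table = ft, groundTruth = ch$groundTruth, runs = ch$runs, config = cfg)
}

# A tiny feature table built directly from a matrix (columns may be any
# grammar names).
makeMatrixTable <- function(X, y) {
  FeatureTable(X, cmContent = y)
}

# The 57 feature names printed in the published selection listings
# (29 from the dd7 feature set, 28 from the dd5 feature set).
printedFeatureNamesFs1 <- function() c(
  "Average DO concentration dd0",
  "Average DO concentration gradient d0",
  "Average DO concentration gradient dd2",
  "Average DO concentration gradient dd6",
  "Average DO concentration gradient dd7",
  "d0 average pH gradient",
  "dd0 average pH gradient",
  "dd0 average acceleration of cell density normalized DO gradient",
  "dd0-dd1 cell density gradient",
  "dd1 aggregate size",
  "dd1 cell density",
  "dd2 average pH",
  "dd7 average pH",
  "dd3 aggregate size",
  "dd3 average acceleration of DO gradient",
  "dd3 average pH gradient",
  "dd3 average acceleration of cell density normalized DO gradient",
  "dd5 average pH gradient",
  "dd5-dd7 aggregate size gradient",
  "dd5-dd7 cell density gradient",
  "dd7 cell density",
  "Cell density normalized DO concentration dd2",
  "Cell density normalized DO concentration dd3",
  "Cell density normalized DO concentration dd7",
  "Average cell density normalized DO concentration gradient dd2",
  "Average cell density normalized DO concentration gradient dd5",
  "Average cell density normalized DO concentration gradient dd7",
  "IWP2 treatment time [h]",
  "Preculture time [h]")

printedFeatureNamesFs2 <- function() c(
  "Average DO concentration d0",
  "Average DO concentration dd0",
  "Average DO concentration dd2",
  "Average DO concentration dd4",
  "Average DO concentration gradient d0",
  "Average DO concentration gradient dd2",
  "Average DO concentration gradient dd4",
  "Average DO concentration gradient dd5",
  "d1 average pH gradient",
  "dd0 aggregate size",
  "dd0 cell density",
  "dd0-dd1 cell density gradient",
  "dd1 average pH",
  "dd1 average acceleration of cell density normalized DO gradient",
  "dd2 aggregate size",
  "dd2 average acceleration of DO gradient",
  "dd2 average pH",
  "dd2 average pH gradient",
  "dd2 average acceleration of cell density normalized DO gradient",
  "dd2-dd3 aggregate size gradient",
  "dd3-dd5 cell density gradient",
  "dd4 average pH gradient",
  "dd5 average acceleration of cell density normalized DO gradient",
  "Cell density normalized DO concentration dd1",
  "Average cell density normalized DO concentration gradient dd5",
  "IWP2 treatment time [h]",
  "Overall aggregate size gradient",
  "Overall density gradient")

# Independent brute-force metric oracle used against the package
# implementation: plain counting, no shared code.
bruteForceMetrics <- function(actual, predicted) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(actual)) {
    if (actual[i] == "insufficient" && predicted[i] == "insufficient") tp <- tp + 1L
    if (actual[i] == "sufficient"   && predicted[i] == "insufficient") fp <- fp + 1L
    if (actual[i] == "sufficient"   && predicted[i] == "sufficient")   tn <- tn + 1L
    if (actual[i] == "insufficient" && predicted[i] == "sufficient")   fn <- fn + 1L
  }
  acc <- (tp + tn) / (tp + tn + fp + fn)
  prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = acc, precision = prec, recall = rec, mcc = mcc)
}
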
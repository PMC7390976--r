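test_that("day windows tile the differentiation time axis", {
  expect_equal(dayWindow("d0"), c(-48, -24))
  expect_equal(dayWindow("d1"), c(-24, 0))
  wins <- unname(t(sapply(paste0("dd", 0:9), dayWindow)))
  expect_equal(wins[1, 1], 0)
  expect_equal(wins[10, 2], 240)
  # no gap, no overlap
  expect_equal(wins[-1, 1], wins[-10, 2])
  expect_error(dayWindow("dd42"), "unknown")
})

test_that("the feature grammar parses and rejects names correctly", {
  p <- parseFeatureName("dopd.accel.dd3")
  expect_equal(p$variable, "dopd")
  expect_equal(p$statistic, "accel")
  expect_equal(p$window, "dd3")
  expect_equal(parseFeatureName("density.grad.dd0_dd1")$window, "dd0_dd1")
  expect_equal(parseFeatureName("meta.iwp2_time")$variable, "meta")
  expect_null(parseFeatureName("do.widget.dd1"))
  expect_null(parseFeatureName("density.grad.dd3_dd1"))  # reversed pair
  expect_null(parseFeatureName("dopd.mean.d0"))          # no preculture density
  expect_null(parseFeatureName("nonsense"))
})

test_that("printed feature names resolve to computable canonical features", {
  printed <- c(printedFeatureNamesFs1(), printedFeatureNamesFs2())
  expect_length(printed, 57)
  canonical <- resolveFeatureName(printed)
  expect_false(anyNA(canonical))
  # every resolved name is a valid grammar name
  expect_true(all(!vapply(canonical, function(n)
    is.null(parseFeatureName(n)), logical(1))))
  # and every one is computable (non-missing) on a complete run
  run <- generateRun(syntheticConfig(nRuns = 1, seed = 3,
                                     samplingInterval = 0.5), runSeed = 99)
  vals <- extractFeatures(run, schema = unique(canonical))
  expect_false(anyNA(vals))
})

test_that("unknown names warn and resolve to NA", {
  expect_warning(out <- resolveFeatureName("dd99 frobnication index"),
                 "unrecognised")
  expect_true(is.na(out))
})

test_that("the default schema holds 101 features covering the printed vocabulary", {
  sch <- defaultFeatureSchema()
  expect_length(sch, 101)
  expect_false(anyDuplicated(sch) > 0)
  printed <- resolveFeatureName(c(printedFeatureNamesFs1(),
                                  printedFeatureNamesFs2()))
  expect_true(all(printed %in% sch))
})

test_that("extraction matches hand-computed values on a linear run", {
  run <- makeManualRun()
  v <- extractFeatures(run)
  # DO(t) = 100 - 0.25 t averaged over dd1 grid (24..47.5 step 0.5, minus the
  # excluded media-change samples in [30, 31.5]) still averages the linear
  # trend; with the exclusion the surviving dd0 mean shifts slightly, so
  # check dd2 (no exclusions): mean t over [48, 71.5] = 59.75
  expect_equal(unname(v["do.mean.dd2"]), 100 - 0.25 * 59.75)
  expect_equal(unname(v["do.grad.dd2"]), -0.25)
  expect_equal(unname(v["do.accel.dd2"]), 0)
  expect_equal(unname(v["ph.grad.dd4"]), 0.001)
  expect_equal(unname(v["density.value.dd1"]), 1.4)
  expect_equal(unname(v["density.grad.dd0_dd1"]), 0.9)
  expect_equal(unname(v["density.grad.dd3_dd5"]), (2.15 - 2.0) / 2)
  expect_equal(unname(v["density.grad.dd5_dd7"]), (2.5 - 2.15) / 2)
  expect_equal(unname(v["density.grad.overall"]), (2.5 - 0.5) / 7)
  expect_equal(unname(v["aggsize.grad.dd2_dd3"]), 20)
  expect_equal(unname(v["meta.iwp2_time"]), 48)
  expect_equal(unname(v["meta.preculture_time"]), 48)
})

test_that("overall offline gradient over explicit endpoints follows the difference quotient", {
  run <- makeManualRun()
  off <- offlineSamples(run)[c(1, 6), ]   # dd0 and dd7 only
  off$density <- c(0.5, 2.5)
  r2 <- BioreactorRun(runMetadata(run), online = run@online, offline = off)
  v <- suppressWarnings(extractFeatures(r2, schema = "density.grad.overall"))
  expect_equal(unname(v), (2.5 - 0.5) / 7)
})

test_that("missingness stays local to the affected day", {
  run <- makeManualRun()
  off <- offlineSamples(run)
  off$density[off$day == "dd5"] <- NA
  r2 <- BioreactorRun(runMetadata(run), online = run@online, offline = off,
                      cmContent = cmContent(run))
  expect_warning(v <- extractFeatures(r2), "not computable")
  expect_true(is.na(v["density.value.dd5"]))
  expect_true(is.na(v["density.grad.dd3_dd5"]))
  expect_true(is.na(v["density.grad.dd5_dd7"]))
  expect_false(is.na(v["density.grad.dd0_dd1"]))
  expect_false(is.na(v["density.value.dd7"]))
  # the overall gradient skips the missing day but stays computable
  expect_equal(unname(v["density.grad.overall"]), (2.5 - 0.5) / 7)
})

test_that("feature-set cutoffs exclude later-day features", {
  co <- makeCohortTable(n = 4, seed = 21)
  fs1 <- suppressWarnings(buildFeatureTable(co$runs, cutoff = "dd7"))
  fs2 <- suppressWarnings(buildFeatureTable(co$runs, cutoff = "dd5"))
  expect_false("density.grad.dd5_dd7" %in% featureNames(fs2))
  expect_false(any(grepl("dd6|dd7", featureNames(fs2))))
  expect_true("do.grad.dd7" %in% featureNames(fs1))
  expect_true("density.grad.dd5_dd7" %in% featureNames(fs1))
  expect_lt(length(featureNames(fs2)), length(featureNames(fs1)))
  # FS2 "overall" gradients are computed within the cutoff
  full <- suppressWarnings(buildFeatureTable(co$runs, cutoff = "none"))
  d5 <- featureValues(fs2)[, "density.grad.overall"]
  dAll <- featureValues(full)[, "density.grad.overall"]
  expect_false(isTRUE(all.equal(d5, dAll)))
})

test_that("a feature-set table equals the table built from cutoff-truncated data", {
  co <- makeCohortTable(n = 3, seed = 31)
  fs2 <- suppressWarnings(buildFeatureTable(co$runs, cutoff = "dd5"))
  truncate <- function(run, tmax) {
    online <- lapply(run@online, function(s) {
      keep <- seriesTimes(s) < tmax
      OnlineSeries(seriesVariable(s), seriesTimes(s)[keep],
                   seriesValues(s)[keep])
    })
    off <- offlineSamples(run)
    BioreactorRun(runMetadata(run), online = online,
                  offline = off[off$time < tmax, ], cmContent = cmContent(run))
  }
  runsT <- lapply(co$runs, truncate, tmax = 144)  # end of dd5
  fs2T <- suppressWarnings(buildFeatureTable(runsT, cutoff = "dd5"))
  expect_equal(featureValues(fs2T), featureValues(fs2))
})

test_that("feature tables refuse duplicate identities", {
  m <- matrix(1:4, 2, 2,
              dimnames = list(c("r1", "r1"), c("do.mean.dd0", "ph.mean.dd0")))
  expect_error(FeatureTable(m), "duplicate run ids")
})
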
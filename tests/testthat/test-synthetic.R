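test_that("generated runs satisfy every container invariant", {
  co <- makeCohortTable(n = 8, seed = 5)
  for (run in co$runs) {
    expect_true(validObject(run, test = TRUE))
    cm <- cmContent(run)
    expect_true(cm >= 0 && cm <= 100)
    # aggregate growth is monotone
    expect_true(all(diff(offlineSamples(run)$aggregate) > 0))
    # one series per variable, strictly increasing times
    for (s in run@online) expect_true(all(diff(seriesTimes(s)) > 0))
  }
})

test_that("cohorts are reproducible from the seed", {
  cfg <- syntheticConfig(nRuns = 4, seed = 17, samplingInterval = 0.5)
  c1 <- generateCohort(cfg)
  c2 <- generateCohort(cfg)
  f1 <- suppressWarnings(buildFeatureTable(c1$runs, "none"))
  f2 <- suppressWarnings(buildFeatureTable(c2$runs, "none"))
  expect_identical(featureValues(f1), featureValues(f2))
  expect_identical(cmContent(f1), cmContent(f2))
  expect_identical(c1$groundTruth$latents, c2$groundTruth$latents)
})

test_that("flagged media-change intervals land on the configured days", {
  cfg <- syntheticConfig(nRuns = 1, seed = 2, samplingInterval = 0.5,
                         mediaChangeDays = c("dd3", "dd5", "dd7"))
  run <- generateRun(cfg, runSeed = 4)
  mc <- mediaChanges(run)
  expect_equal(nrow(mc), 3L)
  days <- floor(mc[, 1] / 24)
  expect_equal(days, c(3, 5, 7))
  expect_true(all(mc[, 2] <= 24 * days + 24))
  # the gap is real: no DO samples inside the first half of each interval
  do <- onlineSeries(run, "DO")
  for (i in 1:3)
    expect_false(any(seriesTimes(do) >= mc[i, 1] &
                       seriesTimes(do) < mc[i, 1] + 0.75))
})

test_that("the noise-free limit reproduces the logistic mean exactly", {
  cfg <- syntheticConfig(nRuns = 6, seed = 8, noiseSdCm = 0,
                         samplingInterval = 0.5,
                         trajectoryParams = list(
                           obsNoise = list(doSd = 0, phSd = 0,
                                           offlineRelSd = 0)))
  ch <- generateCohort(cfg)
  for (i in seq_along(ch$runs))
    expect_equal(cmContent(ch$runs[[i]]), ch$groundTruth$cmNoiseFree[i])
  # and the noise-free CM is the logistic of the planted linear predictor
  gt <- ch$groundTruth
  pe <- gt$plantedEffects
  eta <- gt$beta0 + as.vector(gt$latents[, pe$feature] %*% pe$beta)
  expect_equal(gt$cmNoiseFree, 100 * plogis(eta))
})

test_that("a planted negative coefficient shows up as a negative rank correlation", {
  co <- makeCohortTable(n = 200, seed = 23)
  x <- featureValues(co$table)[, "density.grad.dd0_dd1"]
  cm <- cmContent(co$table)
  expect_lt(spearmanCorrelation(x, cm), 0)   # beta = -0.9 in the defaults
  # and a planted positive one as positive
  x2 <- featureValues(co$table)[, "density.grad.dd5_dd7"]
  expect_gt(spearmanCorrelation(x2, cm), 0)  # beta = +0.8
})

test_that("the class balance matches its target within the exact binomial band", {
  cfg <- syntheticConfig(nRuns = 500, seed = 29, classBalanceTarget = 0.67,
                         samplingInterval = 1)
  ch <- generateCohort(cfg)
  frac <- mean(vapply(ch$runs, cmContent, numeric(1)) < 90)
  ci <- binom.test(round(0.67 * 500), 500, conf.level = 0.99)$conf.int
  expect_gt(frac, ci[1])
  expect_lt(frac, ci[2])
})

test_that("strengthening a planted coefficient does not weaken its cohort correlation", {
  feat <- "density.value.dd1"
  cors <- vapply(c(0.2, 0.8), function(b) {
    pe <- defaultPlantedEffects()
    pe$beta[pe$feature == feat] <- -b
    co <- makeCohortTable(n = 150, seed = 37, plantedEffects = pe)
    abs(cor(featureValues(co$table)[, feat], cmContent(co$table)))
  }, numeric(1))
  expect_gte(cors[2], cors[1])
})

test_that("with no planted effects feature-outcome correlations are null-calibrated", {
  exceed <- 0L; total <- 0L
  for (s in 1:8) {
    co <- makeCohortTable(n = 40, seed = 400 + s,
                          plantedEffects = defaultPlantedEffects()[0, ])
    X <- featureValues(co$table)
    cm <- cmContent(co$table)
    sds <- apply(X, 2, sd)
    X <- X[, sds > 0, drop = FALSE]
    r <- abs(cor(X, cm))
    # two-sided alpha = 0.01 critical value for the Pearson correlation
    n <- nrow(X)
    tcrit <- qt(0.995, df = n - 2)
    rcrit <- tcrit / sqrt(n - 2 + tcrit^2)
    exceed <- exceed + sum(r > rcrit)
    total <- total + length(r)
  }
  rate <- exceed / total
  expect_lt(rate, 0.05)     # close to the nominal 1%
})

test_that("ground-truth tables echo the planted configuration", {
  co <- makeCohortTable(n = 6, seed = 41)
  gt <- describeGroundTruth(co$groundTruth)
  expect_equal(nrow(gt), 6L)
  expect_identical(gt$beta, defaultPlantedEffects()$beta)
  expect_identical(gt$feature, defaultPlantedEffects()$feature)
  # null model: empty table
  co0 <- makeCohortTable(n = 5, seed = 43,
                         plantedEffects = defaultPlantedEffects()[0, ])
  expect_equal(nrow(describeGroundTruth(co0$groundTruth)), 0L)
})

test_that("config validation rejects unusable settings", {
  expect_error(syntheticConfig(nRuns = 0), "nRuns")
  expect_error(syntheticConfig(noiseSdCm = -1), "noiseSdCm")
  expect_error(syntheticConfig(plantedEffects = data.frame(
    feature = "do.mean.dd99", beta = 1)), "not supported")
  expect_error(syntheticConfig(metadataRanges = list(preculture = c(1, 5))),
               "physical bounds")
})
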
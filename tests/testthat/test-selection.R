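test_that("Pearson correlation matches its closed form", {
  expect_equal(pearsonCorrelation(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearsonCorrelation(c(1, 2, 3), c(6, 4, 2)), -1.0)
  r <- pearsonCorrelation(1:4, (1:4)^2)
  expect_gt(r, 0.96); expect_lt(r, 1.0)
  # closed-form oracle on random small cases
  set.seed(7)
  for (k in 1:10) {
    n <- sample(3:6, 1)
    x <- rnorm(n); y <- rnorm(n)
    hand <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pearsonCorrelation(x, y), hand)
  }
  expect_error(pearsonCorrelation(rep(1, 4), 1:4), "constant")
  expect_error(pearsonCorrelation(1:3, 1:4), "equal length")
  expect_error(pearsonCorrelation(1:2, 2:3), "at least 3")
})

test_that("Spearman correlation is rank-based with average ranks on ties", {
  expect_equal(spearmanCorrelation(1:5, (1:5)^3), 1.0)
  expect_equal(spearmanCorrelation(1:5, 5:1), -1.0)
  x <- c(1, 2, 2, 3); y <- c(1, 2, 3, 4)
  expect_equal(spearmanCorrelation(x, y),
               pearsonCorrelation(rank(x), rank(y)))
  expect_error(spearmanCorrelation(rep(2, 3), 1:3), "constant")
})

test_that("PCA matches an independent eigendecomposition", {
  set.seed(13)
  X <- matrix(rnorm(200), 20, 10)
  colnames(X) <- sprintf("glucose.value.dd%d", 0:9)
  ft <- makeMatrixTable(X, rnorm(20))
  res <- pcaReduce(ft, varianceTarget = 0.94)
  d <- selectionDetails(res)
  # oracle: eigendecomposition of the correlation matrix
  eig <- eigen(cor(X), symmetric = TRUE)
  evrOracle <- eig$values / sum(eig$values)
  expect_equal(unname(d$explainedVariance), evrOracle, tolerance = 1e-8)
  for (j in 1:10) {
    dotp <- abs(sum(d$loadings[, j] * eig$vectors[, j]))
    expect_equal(dotp, 1, tolerance = 1e-8)   # same axis up to sign
  }
  # retained count is the minimal one reaching the target
  cum <- cumsum(evrOracle)
  expect_equal(d$nComponents, which(cum >= 0.94)[1])
  expect_true(all(diff(cum) >= -1e-12))
})

test_that("rank-one structure collapses to a single component", {
  x <- rnorm(15)
  X <- cbind(x, 2 * x, 5)    # two perfectly correlated + one constant
  colnames(X) <- c("do.mean.dd0", "do.mean.dd1", "meta.chir_concentration")
  ft <- makeMatrixTable(X, rnorm(15))
  expect_warning(res <- pcaReduce(ft, varianceTarget = 1), "zero-variance")
  d <- selectionDetails(res)
  expect_equal(d$nComponents, 1L)
  expect_equal(unname(d$explainedVariance[1]), 1, tolerance = 1e-12)
})

test_that("permuting feature columns permutes the loadings", {
  set.seed(19)
  X <- matrix(rnorm(120), 12, 10)
  colnames(X) <- sprintf("do.mean.dd%d", 0:9)
  perm <- sample(10)
  r1 <- pcaReduce(makeMatrixTable(X, rnorm(12)))
  r2 <- pcaReduce(makeMatrixTable(X[, perm], rnorm(12)))
  l1 <- selectionDetails(r1)$loadings
  l2 <- selectionDetails(r2)$loadings
  for (j in 1:10)
    expect_equal(abs(unname(l2[, j])), abs(unname(l1[perm, j])),
                 tolerance = 1e-8)
  expect_error(pcaReduce(makeMatrixTable(X, rnorm(12)), varianceTarget = 1.2),
               "varianceTarget")
})

test_that("random-forest importances are normalised and find a strong signal", {
  set.seed(23)
  n <- 80
  X <- matrix(rnorm(n * 6), n, 6)
  colnames(X) <- sprintf("density.value.dd%d", 0:5)
  y <- pmin(100, pmax(0, 70 + 9 * X[, 3] + rnorm(n, 0, 1)))
  signal <- colnames(X)[3]
  res <- rfSelect(makeMatrixTable(X, y), seed = 1)
  expect_equal(sum(featureScores(res)), 1, tolerance = 1e-12)
  expect_true(signal %in% selectedFeatures(res))
  expect_equal(names(which.max(featureScores(res))), signal)
  # selection rule: everything at or above the mean importance
  sc <- featureScores(res)
  expect_setequal(selectedFeatures(res), names(sc)[sc >= mean(sc)])
})

test_that("selection errors on a degenerate outcome", {
  X <- matrix(rnorm(40), 10, 4,
              dimnames = list(NULL, sprintf("do.mean.dd%d", 0:3)))
  ft <- makeMatrixTable(X, rep(90, 10))
  expect_error(rfSelect(ft), "constant")
})

test_that("GP-ARD separates an informative feature from pure noise", {
  wins <- 0L
  for (s in 1:20) {
    set.seed(300 + s)
    n <- 100
    X <- cbind(rnorm(n), rnorm(n))
    colnames(X) <- c("density.value.dd1", "density.value.dd2")
    y <- 70 + 15 * tanh(X[, 1]) + rnorm(n, 0, 2)
    res <- gprArdSelect(makeMatrixTable(X, y), seed = s)
    ls <- selectionDetails(res)$lengthScales
    s1 <- featureScores(res)
    if (ls[1] < ls[2] && s1[1] > s1[2]) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("GP-ARD sensitivities collapse under an outcome independent of all features", {
  maxNull <- numeric(5); maxSig <- numeric(5)
  for (s in 1:5) {
    set.seed(500 + s)
    n <- 60
    X <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(NULL, sprintf("do.mean.dd%d", 0:3)))
    yNull <- rnorm(n, 80, 5)
    ySig <- 80 + 8 * X[, 2] + rnorm(n, 0, 1)
    maxNull[s] <- max(featureScores(gprArdSelect(makeMatrixTable(X, yNull),
                                                 seed = s)))
    maxSig[s] <- max(featureScores(gprArdSelect(makeMatrixTable(X, ySig),
                                                seed = s)))
  }
  # the null sensitivity floor sits far below the planted-signal scale
  # (median across seeds: a single spurious local optimum must not mask
  # the floor)
  expect_lt(median(maxNull), 0.2 * median(maxSig))
})

test_that("duplicated columns keep the planted signal covered", {
  set.seed(61)
  n <- 80
  x <- rnorm(n)
  X <- cbind(x, x, rnorm(n))
  colnames(X) <- c("density.value.dd1", "density.value.dd2", "ph.mean.dd0")
  y <- 75 + 10 * x + rnorm(n, 0, 1)
  res <- gprArdSelect(makeMatrixTable(X, y), seed = 3)
  sel <- selectedFeatures(res)
  expect_true(any(c("density.value.dd1", "density.value.dd2") %in% sel))
  expect_false("ph.mean.dd0" %in% sel && length(sel) == 1L)
})

test_that("MARS selects exactly the feature generating a hinge outcome", {
  set.seed(67)
  n <- 41
  x1 <- seq(0, 1, length.out = n)
  X <- cbind(x1, matrix(rnorm(n * 4), n, 4))
  colnames(X) <- sprintf("aggsize.value.dd%d", 1:5)
  y <- 60 + 30 * pmax(x1 - x1[21], 0)
  res <- marsSelect(makeMatrixTable(X, y))
  expect_identical(selectedFeatures(res), "aggsize.value.dd1")
  # features without retained basis functions are never selected
  expect_true(all(featureScores(res)[setdiff(colnames(X),
                                             selectedFeatures(res))] == 0))
})

test_that("MARS recovers a usable share of planted features on cohorts", {
  pe <- defaultPlantedEffects()$feature
  jac <- vapply(1:6, function(s) {
    co <- makeCohortTable(n = 120, seed = 600 + s)
    sel <- selectedFeatures(suppressWarnings(marsSelect(co$table)))
    length(intersect(sel, pe)) / length(union(sel, pe))
  }, numeric(1))
  expect_gte(mean(jac), 0.3)
})

test_that("selection recall does not degrade with cohort size", {
  pe <- defaultPlantedEffects()$feature
  recall <- vapply(c(40, 100, 400), function(n) {
    mean(vapply(1:3, function(s) {
      co <- makeCohortTable(n = n, seed = 700 + s)
      mean(pe %in% selectedFeatures(suppressWarnings(
        rfSelect(co$table, seed = s))))
    }, numeric(1)))
  }, numeric(1))
  expect_gte(recall[2], recall[1] - 1 / 12)
  expect_gte(recall[3], recall[2] - 1 / 12)
})

test_that("the dispatcher routes to every method", {
  co <- makeCohortTable(n = 25, seed = 71)
  for (m in c("pearson", "spearman", "pca", "rf", "mars")) {
    res <- suppressWarnings(selectFeatures(co$table, m))
    expect_s4_class(res, "SelectionResult")
    expect_identical(selectionMethod(res), m)
  }
})
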
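test_that("the 90% threshold rule resolves the boundary upward", {
  expect_equal(as.character(classifyCm(92)), "sufficient")
  expect_equal(as.character(classifyCm(89.9)), "insufficient")
  expect_equal(as.character(classifyCm(90)), "sufficient")
  expect_error(classifyCm(104), "\\[0, 100\\]")
  expect_error(classifyCm(50, threshold = 0), "threshold")
})

test_that("raising the threshold never flips insufficient to sufficient", {
  grid <- seq(0, 100, by = 2.5)
  for (th in c(80, 90, 95)) {
    lo <- classifyCm(grid, th)
    hi <- classifyCm(grid, th + 4)
    flipped <- lo == "insufficient" & hi == "sufficient"
    expect_false(any(flipped))
  }
})

test_that("random-forest backends honour the 5-tree default and the seed", {
  co <- makeCohortTable(n = 20, seed = 51)
  m <- trainModel(co$table, "rf_regressor", seed = 4)
  expect_equal(m@fit$rf$ntree, 5L)
  m2 <- trainModel(co$table, "rf_regressor", seed = 4)
  probe <- featureValues(co$table)[1:5, ]
  expect_identical(predictCm(m, probe), predictCm(m2, probe))
  mc <- trainModel(co$table, "rf_classifier", seed = 4)
  expect_equal(mc@fit$rf$ntree, 5L)
})

test_that("GP regression reproduces noise-free linear training data", {
  x <- seq(0, 1, length.out = 20)
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "density.value.dd1"))
  y <- 60 + 30 * x              # CM percent scale
  ft <- makeMatrixTable(X, y)
  m <- trainModel(ft, "gpr", seed = 1)
  expect_lt(max(abs(predictCm(m, ft) - y)), 1e-3)
})

test_that("predictions are clipped to the percent domain", {
  x <- seq(0, 1, length.out = 21)
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "density.value.dd1"))
  ft <- makeMatrixTable(X, 90 + 10 * x)   # extrapolates past 100
  m <- trainModel(ft, "mars", seed = 1)
  hi <- predictCm(m, matrix(5, 1, 1, dimnames = list(NULL, "density.value.dd1")))
  lo <- predictCm(m, matrix(-20, 1, 1, dimnames = list(NULL, "density.value.dd1")))
  expect_equal(unname(hi), 100)
  expect_equal(unname(lo), 0)
})

test_that("class predictions compose classify with the regression prediction", {
  co <- makeCohortTable(n = 25, seed = 53)
  for (backend in c("rf_regressor", "gpr", "mars")) {
    m <- trainModel(co$table, backend, seed = 2)
    probe <- featureValues(co$table)
    expect_identical(predictClass(m, probe),
                     classifyCm(predictCm(m, probe), modelThreshold(m)))
  }
})

test_that("the direct classifier separates separable data and refuses predictCm", {
  x <- c(seq(0, 0.4, length.out = 10), seq(0.6, 1, length.out = 10))
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "density.value.dd1"))
  y <- c(rep(70, 10), rep(95, 10))      # perfectly separable at x = 0.5
  ft <- makeMatrixTable(X, y)
  m <- trainModel(ft, "rf_classifier", seed = 1, settings = list(ntree = 25))
  pred <- predictClass(m, ft)
  expect_identical(as.character(unname(pred)), as.character(classifyCm(y)))
  expect_error(predictCm(m, ft), "undefined")
})

test_that("prediction demands exactly the training features", {
  co <- makeCohortTable(n = 12, seed = 57)
  m <- trainModel(co$table, "rf_regressor",
                  features = c("density.value.dd1", "ph.grad.dd0"), seed = 1)
  probe <- featureValues(co$table)[, "density.value.dd1", drop = FALSE]
  expect_error(predictCm(m, probe), "ph.grad.dd0")
  expect_error(trainModel(co$table, "rf_regressor",
                          features = "do.mean.dd99"), "unknown feature")
})

test_that("training rejects degenerate inputs", {
  X <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(trainModel(makeMatrixTable(X, c(90, 91, 92, 93)),
                          "rf_regressor"), "at least 5")
  X2 <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(trainModel(makeMatrixTable(X2, rep(80, 6)), "gpr"), "constant")
  expect_error(trainModel(makeMatrixTable(X2, rep(c(95, 96), 3)),
                          "rf_classifier"), "single class")
})

test_that("imputation medians are learned on training data and reused", {
  set.seed(61)
  X <- matrix(rnorm(40, 10), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- 70 + 3 * X[, 1] + rnorm(20, 0, 0.5)
  ft <- makeMatrixTable(X, pmin(100, pmax(0, y)))
  m <- trainModel(ft, "rf_regressor", seed = 1)
  probe <- X[1:2, ]
  probe[1, "b"] <- NA
  pred <- predictCm(m, probe)
  probeFilled <- X[1:2, ]
  probeFilled[1, "b"] <- median(X[, "b"])
  expect_identical(pred, predictCm(m, probeFilled))
})
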
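## Gaussian-process regression with a radial-basis-function kernel.
##
##   k(x, x') = sf2 * exp(-0.5 * sum_d (x_d - x'_d)^2 / ell_d^2) + sn2 * 1{x = x'}
##
## Hyperparameters (signal variance sf2, noise variance sn2 and either one
## shared length-scale or one per feature for automatic relevance
## determination, ARD) are optimised by the exact log marginal likelihood
## with analytic gradients (L-BFGS-B on log-parameters). Under ARD an
## irrelevant feature's length-scale grows large, removing it from the
## kernel; the inverse length-scale is therefore a relevance score, sharpened
## further by the posterior-mean sensitivity analysis in gprArdSelect().
##
## X is expected standardised (z-scored) by the caller; y is centred/scaled
## internally.

.gpSqDist <- function(Xs) {
  r <- rowSums(Xs^2)
  d2 <- outer(r, r, "+") - 2 * tcrossprod(Xs)
  d2[d2 < 0] <- 0
  d2
}

## theta = c(log sf2, log sn2, log ell[1..q]); q = 1 (isotropic) or p (ARD)
.gpNll <- function(theta, X, y, DD = NULL) {
  n <- length(y); p <- ncol(X)
  sf2 <- exp(theta[1L]); sn2 <- exp(theta[2L])
  ell <- exp(theta[-(1:2)])
  if (length(ell) == 1L) ell <- rep(ell, p)
  Xs <- sweep(X, 2L, ell, "/")
  K0 <- sf2 * exp(-0.5 * .gpSqDist(Xs))
  K <- K0 + diag(sn2 + 1e-8, n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(list(value = 1e10, gradient = rep(0, length(theta))))
  alpha <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
  nll <- 0.5 * sum(y * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
  Kinv <- chol2inv(ch)
  W <- tcrossprod(alpha) - Kinv            # dlogml/dtheta = 0.5 tr(W dK)
  g <- numeric(length(theta))
  g[1L] <- -0.5 * sum(W * K0)              # d/d log sf2
  g[2L] <- -0.5 * sn2 * sum(diag(W))       # d/d log sn2
  if (length(theta) == 3L) {
    d2 <- .gpSqDist(Xs)
    g[3L] <- -0.5 * sum(W * (K0 * d2))     # d/d log ell (shared)
  } else {
    WK <- as.vector(W * K0)
    ## DD[, d] = vec(outer squared differences of feature d)
    g[-(1:2)] <- -0.5 * as.vector(crossprod(DD, WK)) / ell^2
  }
  list(value = nll, gradient = g)
}

.gpFit <- function(X, y, ard = FALSE, restarts = if (ard) 1L else 5L,
                   seed = 1L, maxit = 150L) {
  X <- as.matrix(X); n <- nrow(X); p <- ncol(X)
  if (n < 3L) stop("need at least 3 training points")
  yMean <- mean(y); ySd <- stats::sd(y)
  if (!is.finite(ySd) || ySd == 0) stop("constant outcome")
  ys <- (y - yMean) / ySd
  q <- if (ard) p else 1L
  DD <- NULL
  if (ard) {
    DD <- matrix(0, n * n, p)
    for (d in seq_len(p)) {
      xd <- X[, d]
      DD[, d] <- as.vector(outer(xd, xd, "-")^2)
    }
  }
  obj <- function(th) .gpNll(th, X, ys, DD)$value
  grd <- function(th) .gpNll(th, X, ys, DD)$gradient
  ## length-scale floor: below ~0.1 SD (ARD inputs are z-scored) the kernel
  ## merely interpolates observation noise
  ellFloor <- if (ard) log(0.1) else log(1e-2)
  starts <- .withSeed(.childSeed(seed, 77L), {
    lapply(seq_len(restarts), function(r) {
      if (r == 1L) c(log(0.5), log(0.5), rep(log(sqrt(p)), q))
      else c(stats::rnorm(1, 0, 0.5), log(0.1) + stats::rnorm(1, 0, 0.5),
             stats::rnorm(q, log(sqrt(p)), 0.7))
    })
  })
  best <- NULL
  for (th0 in starts) {
    opt <- tryCatch(
      stats::optim(th0, obj, grd, method = "L-BFGS-B",
                   lower = c(-8, -13, rep(ellFloor, q)),
                   upper = c(8, 5, rep(log(1e4), q)),
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("GP hyperparameter optimisation failed in all ", restarts,
         " restart(s)")
  th <- best$par
  sf2 <- exp(th[1L]); sn2 <- exp(th[2L])
  ell <- exp(th[-(1:2)]); if (!ard) ell <- rep(ell, p)
  Xs <- sweep(X, 2L, ell, "/")
  K <- sf2 * exp(-0.5 * .gpSqDist(Xs)) + diag(sn2 + 1e-8, n)
  ch <- chol(K)
  alpha <- backsolve(ch, backsolve(ch, ys, transpose = TRUE))
  structure(list(X = X, alpha = alpha, ell = ell, sf2 = sf2, sn2 = sn2,
                 yMean = yMean, ySd = ySd, ard = ard, nll = best$value),
            class = "gpFit")
}

## Posterior mean at new inputs.
.gpPredict <- function(fit, Xnew) {
  Xnew <- as.matrix(Xnew)
  Xs <- sweep(fit$X, 2L, fit$ell, "/")
  Ns <- sweep(Xnew, 2L, fit$ell, "/")
  d2 <- outer(rowSums(Ns^2), rowSums(Xs^2), "+") - 2 * tcrossprod(Ns, Xs)
  d2[d2 < 0] <- 0
  Kst <- fit$sf2 * exp(-0.5 * d2)
  as.vector(Kst %*% fit$alpha) * fit$ySd + fit$yMean
}

## Mean squared partial derivative of the posterior mean at the training
## points, by central finite differences (the ARD sensitivity score).
.gpSensitivity <- function(fit, h = 1e-3) {
  X <- fit$X; p <- ncol(X)
  s <- numeric(p)
  for (j in seq_len(p)) {
    Xp <- X; Xm <- X
    Xp[, j] <- Xp[, j] + h
    Xm[, j] <- Xm[, j] - h
    dj <- (.gpPredict(fit, Xp) - .gpPredict(fit, Xm)) / (2 * h)
    s[j] <- mean(dj^2)
  }
  s
}
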
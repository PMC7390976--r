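## Multivariate adaptive regression splines (additive form).
##
## The model is a linear combination of an intercept and hinge basis
## functions max(x_j - t, 0) / max(t - x_j, 0). The forward pass greedily
## adds the reflected hinge pair with the largest residual-sum-of-squares
## reduction (candidate knots on a per-feature quantile grid); the backward
## pass prunes terms by generalised cross-validation,
##   GCV(M) = RSS / (n * (1 - C(M)/n)^2),  C(M) = M + penalty * (M - 1),
## keeping the subset with the smallest GCV. Features appearing in at least
## one retained basis function are the MARS-selected features.

.marsKnots <- function(x, nKnots) {
  u <- sort(unique(x))
  if (length(u) <= 2L) return(numeric(0))
  interior <- u[-c(1L, length(u))]
  if (length(interior) <= nKnots) return(interior)
  ## odd default knot count keeps the median on the grid (type-1 quantiles
  ## stay on observed values)
  unique(stats::quantile(interior, probs = seq(0.05, 0.95, length.out = nKnots),
                         names = FALSE, type = 1L))
}

.marsBasis <- function(X, terms) {
  B <- matrix(1, nrow(X), length(terms) + 1L)
  for (i in seq_along(terms)) {
    tm <- terms[[i]]
    x <- X[, tm$feature]
    B[, i + 1L] <- if (tm$dir > 0) pmax(x - tm$knot, 0) else pmax(tm$knot - x, 0)
  }
  B
}

.marsGcv <- function(rss, n, m, penalty) {
  cm <- m + penalty * (m - 1)
  if (cm >= n) return(Inf)
  rss / n / (1 - cm / n)^2
}

.marsFit <- function(X, y, maxTerms = 21L, nKnots = 11L, penalty = 2,
                     minGain = 1e-10) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (any(!is.finite(X)) || any(!is.finite(y))) stop("non-finite inputs")
  tss <- sum((y - mean(y))^2)
  if (tss == 0) {
    return(structure(list(terms = list(), coef = mean(y),
                          featureNames = colnames(X), gcv = 0),
                     class = "marsFit"))
  }
  ## candidate hinge pairs: (feature, knot)
  cand <- do.call(rbind, lapply(seq_len(p), function(j) {
    ks <- .marsKnots(X[, j], nKnots)
    if (!length(ks)) return(NULL)
    cbind(feature = j, knot = ks)
  }))
  terms <- list()
  if (!is.null(cand)) {
    K <- nrow(cand)
    Hpos <- matrix(0, n, K); Hneg <- matrix(0, n, K)
    for (k in seq_len(K)) {
      x <- X[, cand[k, 1L]]
      Hpos[, k] <- pmax(x - cand[k, 2L], 0)
      Hneg[, k] <- pmax(cand[k, 2L] - x, 0)
    }
    used <- rep(FALSE, K)
    B <- matrix(1, n, 1L)
    repeat {
      if (ncol(B) + 2L > maxTerms) break
      qrB <- qr(B)
      Q <- qr.Q(qrB)
      r <- y - Q %*% crossprod(Q, y)
      rssCur <- sum(r^2)
      A <- Hpos - Q %*% crossprod(Q, Hpos)
      Bn <- Hneg - Q %*% crossprod(Q, Hneg)
      aa <- colSums(A^2); bb <- colSums(Bn^2); ab <- colSums(A * Bn)
      ar <- as.vector(crossprod(A, r)); br <- as.vector(crossprod(Bn, r))
      det <- aa * bb - ab^2
      eps <- 1e-10 * max(aa * bb, 1)
      gainPair <- ifelse(det > eps,
                         (bb * ar^2 - 2 * ab * ar * br + aa * br^2) / det, -Inf)
      gainA <- ifelse(aa > 1e-12, ar^2 / aa, -Inf)
      gainB <- ifelse(bb > 1e-12, br^2 / bb, -Inf)
      gain <- pmax(gainPair, gainA, gainB)
      gain[used] <- -Inf
      kBest <- which.max(gain)
      if (!is.finite(gain[kBest]) || gain[kBest] < minGain * tss) break
      used[kBest] <- TRUE
      j <- cand[kBest, 1L]; t0 <- cand[kBest, 2L]
      terms <- c(terms, list(list(feature = j, knot = t0, dir = 1),
                             list(feature = j, knot = t0, dir = -1)))
      B <- cbind(B, Hpos[, kBest], Hneg[, kBest])
    }
  }
  ## backward pruning by GCV over the deletion sequence
  fitRss <- function(sel) {
    Bm <- .marsBasis(X, terms[sel])
    f <- stats::lm.fit(Bm, y)
    sum(f$residuals^2)
  }
  nT <- length(terms)
  bestSel <- integer(0)
  bestGcv <- .marsGcv(tss, n, 1L, penalty)
  sel <- seq_len(nT)
  if (nT) {
    g <- .marsGcv(fitRss(sel), n, nT + 1L, penalty)
    if (g < bestGcv) { bestGcv <- g; bestSel <- sel }
    while (length(sel) > 0L) {
      rssDrop <- vapply(seq_along(sel),
                        function(i) fitRss(sel[-i]), numeric(1))
      i <- which.min(rssDrop)
      sel <- sel[-i]
      g <- .marsGcv(rssDrop[i], n, length(sel) + 1L, penalty)
      if (g < bestGcv) { bestGcv <- g; bestSel <- sel }
    }
  }
  terms <- terms[bestSel]
  Bm <- .marsBasis(X, terms)
  f <- stats::lm.fit(Bm, y)
  co <- f$coefficients
  keep <- which(!is.na(co[-1L]) & abs(co[-1L]) > 0)
  terms <- terms[keep]
  Bm <- .marsBasis(X, terms)
  f <- stats::lm.fit(Bm, y)
  structure(list(terms = terms, coef = f$coefficients,
                 featureNames = colnames(X),
                 gcv = .marsGcv(sum(f$residuals^2), n, length(terms) + 1L,
                                penalty)),
            class = "marsFit")
}

.marsPredict <- function(fit, Xnew) {
  Xnew <- as.matrix(Xnew)
  Bm <- .marsBasis(Xnew, fit$terms)
  co <- fit$coef
  co[is.na(co)] <- 0
  as.vector(Bm %*% co)
}

.marsSelected <- function(fit) {
  if (!length(fit$terms)) return(character(0))
  unique(fit$featureNames[vapply(fit$terms, `[[`, numeric(1), "feature")])
}
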
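## Synthetic bioreactor-run generator
## ----------------------------------
## Emulates the qualitative trajectory phenomenology of stirred-tank hiPSC
## cardiac differentiation runs -- saturating cell-density kinetics,
## density-coupled dissolved-oxygen decline, lactate-driven pH drift with
## media-change resets, glucose sawtooth, cube-root-like aggregate growth --
## and plants configurable effects of engineered features on the endpoint
## cardiomyocyte content through a logistic link:
##
##   CM% = 100 * logistic(beta0 + sum_j beta_j * z_j) + noise, clipped to [0,100]
##
## where each latent z_j manifests (up to observation noise) in one engineered
## feature, so that recovery of planted features by the selection methods is a
## well-posed end-to-end test. Effects are defined on engineered-feature
## scales; the generator inverts each feature definition to shape the raw
## trajectories.

.PLANTED_CHANNELS <- c("density.grad.dd0_dd1", "density.value.dd1",
                       "density.grad.dd5_dd7", "dopd.grad.dd2",
                       "ph.grad.dd0", "meta.iwp2_time")

#' Feature channels the generator can plant effects on
#' @return Character vector of canonical feature names.
#' @export
supportedPlantedFeatures <- function() .PLANTED_CHANNELS

#' Default planted feature-outcome effects
#'
#' Mirrors the biologically motivated signals of the modelled process: the
#' early (dd0-dd1) cell-density gradient and dd1 density (paracrine-factor
#' accumulation during mesoderm priming), the IWP2 residence time (temporal
#' WNT inhibition), the dd2 density-normalised DO gradient (per-cell oxygen
#' demand during specification), the late dd5-dd7 density gradient
#' (progenitor expansion) and the dd0 pH drift. Coefficients are on the
#' logit scale per standard deviation of the latent.
#'
#' @return `data.frame` with columns `feature` and `beta`.
#' @export
defaultPlantedEffects <- function() {
  data.frame(
    feature = c("density.grad.dd0_dd1", "density.value.dd1", "meta.iwp2_time",
                "dopd.grad.dd2", "density.grad.dd5_dd7", "ph.grad.dd0"),
    beta = c(-0.9, -0.8, -0.9, 0.7, 0.8, -0.6),
    stringsAsFactors = FALSE)
}

.defaultTrajectoryParams <- function() list(
  doSetpoint = list(mean = 95, sd = 2),          # % air saturation
  oxygenCoef = list(mean = 12, sd = 1.2),        # % per (1e6 cells/mL)
  metabolicPeak = list(mean = 1.8, sd = 0.15),   # demand multiplier by dd5
  lactateRate = list(mean = 2.2, sd = 0.25),     # mmol/L/day per 1e6 cells/mL
  glucoseRate = list(mean = 2.6, sd = 0.3),
  lactatePhCoupling = 0.026,                     # pH units per mmol/L lactate
  phBase = list(mean = 7.35, sd = 0.04),
  phGradDd0 = list(mean = -0.10, sd = 0.03),     # pH/day planted channel
  densityDd1 = list(mean = 1.35, sd = 0.3),      # 1e6 cells/mL planted channel
  densityGradDd0Dd1 = list(mean = 0.9, sd = 0.6),# 1e6 cells/mL/day planted
  lateGrad = list(mean = 0.1, sd = 0.35),        # dd5-dd7 density gradient
  dopdGradDd2 = list(mean = -0.02, sd = 0.05),   # %/(1e6 cells/mL)/h planted
  growthFactors = list(mean = c(0.25, 0.12, 0.05, 0.0),
                       sd = c(0.08, 0.06, 0.05, 0.04)),  # dd1..dd5 increments
  aggregateBase = list(mean = 120, sd = 12),     # um at dd0
  aggregateExponent = list(mean = 1 / 3, relSd = 0.12),
  aggregateGrowth = 0.9,                         # per day inside (1 + g*t)^e
  obsNoise = list(doSd = 0.8, phSd = 0.01, offlineRelSd = 0.01)
)

.defaultMetadataRanges <- function() list(
  preculture = c(45, 56),   # h
  iwp2Default = 48,         # h
  iwp2ModProb = 0.5,        # fraction of runs with modulated IWP2 time
  iwp2Step = 12,            # h per modulation unit
  chir = 5,                 # uM
  rotation = c(55, 65)      # rpm
)

#' Configuration of the synthetic cohort generator
#'
#' @param nRuns Number of runs (the emulated study collected 58).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param classBalanceTarget Target fraction of insufficient (< 90\% CM)
#'   runs; the logistic intercept is calibrated analytically to it.
#' @param plantedEffects `data.frame` with columns `feature` (canonical names
#'   among [supportedPlantedFeatures()]) and `beta`; may have zero rows for a
#'   null cohort.
#' @param noiseSdCm Gaussian noise (percentage points) added to the noise-free
#'   CM content before clipping to `[0, 100]`.
#' @param samplingInterval Online sampling interval in hours.
#' @param mediaChangeDays Day labels on which media is partially exchanged;
#'   each gets a flagged interval with a measurement gap and a rectangular
#'   DO/pH excursion.
#' @param offlineDays Day labels with offline sampling.
#' @param trajectoryParams Named list overriding entries of the default
#'   trajectory parameter set (means/SDs of setpoints, rates, couplings and
#'   observation noise).
#' @param metadataRanges Named list overriding the metadata sampling ranges.
#' @return A validated `SyntheticConfig` (list).
#' @examples
#' cfg <- syntheticConfig(nRuns = 5, seed = 1)
#' @export
syntheticConfig <- function(nRuns = 58, seed = 1, classBalanceTarget = 2 / 3,
                            plantedEffects = defaultPlantedEffects(),
                            noiseSdCm = 3, samplingInterval = 0.25,
                            mediaChangeDays = c("dd1", "dd3", "dd5", "dd7"),
                            offlineDays = c("dd0", "dd1", "dd2", "dd3",
                                            "dd5", "dd7"),
                            trajectoryParams = list(),
                            metadataRanges = list()) {
  cfg <- list(
    nRuns = as.integer(nRuns), seed = as.integer(seed),
    classBalanceTarget = classBalanceTarget,
    plantedEffects = plantedEffects, noiseSdCm = noiseSdCm,
    samplingInterval = samplingInterval,
    mediaChangeDays = mediaChangeDays, offlineDays = offlineDays,
    trajectoryParams = utils::modifyList(.defaultTrajectoryParams(),
                                         trajectoryParams),
    metadataRanges = utils::modifyList(.defaultMetadataRanges(),
                                       metadataRanges))
  class(cfg) <- "SyntheticConfig"
  .validateSyntheticConfig(cfg)
  cfg
}

.validateSyntheticConfig <- function(cfg) {
  if (cfg$nRuns < 1L) stop("nRuns must be >= 1")
  if (cfg$noiseSdCm < 0) stop("noiseSdCm must be >= 0")
  if (cfg$classBalanceTarget < 0 || cfg$classBalanceTarget > 1)
    stop("classBalanceTarget must lie in [0, 1]")
  pe <- cfg$plantedEffects
  if (nrow(pe)) {
    bad <- !pe$feature %in% .PLANTED_CHANNELS
    if (any(bad))
      stop("planted feature(s) not supported by the generator: ",
           paste(pe$feature[bad], collapse = ", "))
    if (anyDuplicated(pe$feature)) stop("duplicate planted features")
  }
  mr <- cfg$metadataRanges
  if (mr$preculture[1] < 24 || mr$preculture[2] > 120)
    stop("preculture range outside physical bounds [24, 120] h")
  if (!all(cfg$mediaChangeDays %in% paste0("dd", 0:10)))
    stop("mediaChangeDays must be differentiation day labels")
  invisible(cfg)
}

## Evaluate an expression under a temporary RNG state.
.withSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (hasSeed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

## Logistic intercept such that P(noise-free CM < 90) matches the balance
## target: beta0 = logit(0.9) - sd(sum beta_j z_j) * qnorm(target).
.calibrateIntercept <- function(cfg) {
  pe <- cfg$plantedEffects
  if (!nrow(pe)) return(stats::qlogis(0.9))
  vars <- ifelse(pe$feature == "meta.iwp2_time",
                 cfg$metadataRanges$iwp2ModProb, 1)
  sdS <- sqrt(sum(pe$beta^2 * vars))
  stats::qlogis(0.9) - sdS * stats::qnorm(cfg$classBalanceTarget)
}

.generateRunFull <- function(cfg, runSeed, latents, runId = NULL) {
  tp <- cfg$trajectoryParams; mr <- cfg$metadataRanges
  z <- structure(numeric(length(.PLANTED_CHANNELS)),
                 names = .PLANTED_CHANNELS)
  cont <- setdiff(.PLANTED_CHANNELS, "meta.iwp2_time")
  z[cont] <- latents[cont]
  .withSeed(runSeed, {
    ## -- metadata ---------------------------------------------------------
    preT <- round(stats::runif(1, mr$preculture[1], mr$preculture[2]))
    modulated <- stats::runif(1) < mr$iwp2ModProb
    u <- sample(c(-2, -1, 1, 2), 1L)
    iwp2 <- if (modulated) mr$iwp2Default + mr$iwp2Step * u else mr$iwp2Default
    z["meta.iwp2_time"] <- if (modulated) u / sqrt(2.5) else 0
    rotation <- round(stats::runif(1, mr$rotation[1], mr$rotation[2]))
    mcDays <- .ddIndex(cfg$mediaChangeDays)
    mcStart <- 24 * mcDays + 6
    mediaChanges <- cbind(start = mcStart, end = mcStart + 1.5)
    if (is.null(runId)) runId <- sprintf("run_s%d", runSeed)
    md <- RunMetadata(runId, precultureTime = preT, iwp2TreatmentTime = iwp2,
                      chirConcentration = mr$chir, rotationSpeed = rotation,
                      mediaChanges = mediaChanges)

    ## -- density anchors at integer differentiation days ------------------
    V1 <- max(0.3, tp$densityDd1$mean +
                tp$densityDd1$sd * z["density.value.dd1"])
    G01 <- tp$densityGradDd0Dd1$mean +
      tp$densityGradDd0Dd1$sd * z["density.grad.dd0_dd1"]
    N <- numeric(11)                      # days 0..10
    N[2] <- V1
    N[1] <- max(0.15, V1 - G01)
    f <- stats::rnorm(4, tp$growthFactors$mean, tp$growthFactors$sd)
    for (k in 2:5) N[k + 1] <- max(0.2, N[k] * (1 + f[k - 1]))
    G57 <- tp$lateGrad$mean + tp$lateGrad$sd * z["density.grad.dd5_dd7"]
    N[8] <- max(0.2, N[6] + 2 * G57)
    N[7] <- (N[6] + N[8]) / 2
    N[9:11] <- N[8] * c(0.98, 0.96, 0.94)

    ## -- continuous trajectories ------------------------------------------
    dt <- cfg$samplingInterval
    tgrid <- seq(-preT, 240, by = dt)
    len <- length(tgrid)
    Npre <- pmin(0.5 * exp(log(2) * (tgrid + preT) / 30), 2.5)
    Ndiff <- stats::approx(24 * (0:10), N, xout = pmax(tgrid, 0), rule = 2)$y
    Nt <- ifelse(tgrid < 0, Npre, Ndiff)
    Npos <- pmax(Nt, 0.05)
    mPeak <- max(1, stats::rnorm(1, tp$metabolicPeak$mean, tp$metabolicPeak$sd))
    mt <- stats::approx(c(-60, 24, 120, 240), c(1, 1, mPeak, mPeak),
                        xout = tgrid, rule = 2)$y
    at <- stats::approx(c(-60, 96, 240), c(1, 1, 0.35), xout = tgrid,
                        rule = 2)$y
    SP <- stats::rnorm(1, tp$doSetpoint$mean, tp$doSetpoint$sd)
    kO <- max(1, stats::rnorm(1, tp$oxygenCoef$mean, tp$oxygenCoef$sd))
    dopd <- (SP - kO * Nt * mt) / Npos
    ## plant the dd2 mean gradient of the density-normalised DO signal by a
    ## continuous ramp (constant after the window keeps DO continuous)
    w2 <- which(tgrid >= 48 & tgrid < 72)
    baseGrad <- mean(diff(dopd[w2])) / dt
    targetGrad <- tp$dopdGradDd2$mean + tp$dopdGradDd2$sd * z["dopd.grad.dd2"]
    dopd <- dopd + (targetGrad - baseGrad) * pmin(pmax(tgrid - 48, 0), 24)
    DOt <- dopd * Npos

    ## -- nutrients (Euler with media-change resets) ------------------------
    kL <- max(0.3, stats::rnorm(1, tp$lactateRate$mean, tp$lactateRate$sd)) / 24
    kG <- max(0.3, stats::rnorm(1, tp$glucoseRate$mean, tp$glucoseRate$sd)) / 24
    Lfresh <- 0.2; Gfresh <- 25
    ## full medium exchange at induction (t = 0), partial (100/150 mL) at the
    ## flagged media changes; Euler increments accumulated per segment
    resets <- sort(c(0, mcStart))
    Lcur <- Lfresh; Gcur <- Gfresh
    Lt <- numeric(len); Gt <- numeric(len)
    bounds <- c(-Inf, resets, Inf)
    incL <- c(0, (kL * Npos * at)[-len] * dt)
    incG <- c(0, (kG * Npos * at)[-len] * dt)
    for (b in seq_len(length(bounds) - 1L)) {
      idx <- which(tgrid > bounds[b] & tgrid <= bounds[b + 1L])
      if (b == 1L) idx <- which(tgrid <= bounds[2L])
      if (!length(idx)) next
      segL <- Lcur + cumsum(incL[idx]) - incL[idx[1L]]
      segG <- pmax(0.2, Gcur - cumsum(incG[idx]) + incG[idx[1L]])
      Lt[idx] <- segL; Gt[idx] <- segG
      ev <- bounds[b + 1L]
      if (is.finite(ev)) {
        if (ev == 0) { Lcur <- Lfresh; Gcur <- Gfresh }
        else { Lcur <- segL[length(segL)] / 3
               Gcur <- segG[length(segG)] +
                 (2 / 3) * (Gfresh - segG[length(segG)]) }
      }
    }

    ## -- pH ----------------------------------------------------------------
    phBase <- stats::rnorm(1, tp$phBase$mean, tp$phBase$sd)
    s0 <- (tp$phGradDd0$mean + tp$phGradDd0$sd * z["ph.grad.dd0"]) / 24
    pHt <- phBase - tp$lactatePhCoupling * (Lt - Lfresh) +
      s0 * pmin(pmax(tgrid, 0), 24)

    ## -- observation noise, artifacts, clipping ---------------------------
    on <- tp$obsNoise
    DOobs <- DOt + stats::rnorm(len, 0, on$doSd)
    pHobs <- pHt + stats::rnorm(len, 0, on$phSd)
    ## media-change artifact: measurement gap in the first half of the
    ## flagged interval, rectangular excursion in the second half
    drop <- rep(FALSE, len); bump <- rep(FALSE, len)
    for (i in seq_along(mcStart)) {
      s <- mediaChanges[i, 1L]; e <- mediaChanges[i, 2L]
      drop <- drop | (tgrid >= s & tgrid < s + 0.75)
      bump <- bump | (tgrid >= s + 0.75 & tgrid <= e)
    }
    DOobs[bump] <- DOobs[bump] + 12
    pHobs[bump] <- pHobs[bump] + 0.12
    DOobs <- pmin(pmax(DOobs, 0.5), 199.5)
    pHobs <- pmin(pmax(pHobs, 4.1), 9.9)
    keep <- !drop
    online <- list(OnlineSeries("DO", tgrid[keep], DOobs[keep]),
                   OnlineSeries("pH", tgrid[keep], pHobs[keep]))

    ## -- offline table -----------------------------------------------------
    offDays <- cfg$offlineDays
    offIdx <- .ddIndex(offDays)
    offTimes <- 24 * offIdx + 6
    gridAt <- function(tt) vapply(tt, function(t0)
      which.min(abs(tgrid - t0)), integer(1))
    gi <- gridAt(offTimes)
    relNoise <- function(n) 1 + stats::rnorm(n, 0, on$offlineRelSd)
    A0 <- stats::rnorm(1, tp$aggregateBase$mean, tp$aggregateBase$sd)
    ex <- tp$aggregateExponent$mean *
      (1 + tp$aggregateExponent$relSd * stats::rnorm(1))
    offline <- data.frame(
      day = offDays,
      time = offTimes,
      density = pmax(0.05, N[offIdx + 1L] * relNoise(length(offDays))),
      aggregate = A0 * (1 + tp$aggregateGrowth * offIdx)^ex,
      glucose = pmax(0.1, Gt[gi] * relNoise(length(offDays))),
      lactate = pmax(0, Lt[gi] * relNoise(length(offDays))),
      stringsAsFactors = FALSE)

    ## -- endpoint ----------------------------------------------------------
    pe <- cfg$plantedEffects
    beta0 <- .calibrateIntercept(cfg)
    eta <- beta0 + if (nrow(pe)) sum(pe$beta * z[pe$feature]) else 0
    cmMean <- 100 * stats::plogis(eta)
    cm <- min(100, max(0, cmMean + stats::rnorm(1, 0, cfg$noiseSdCm)))

    list(run = BioreactorRun(md, online = online, offline = offline,
                             cmContent = cm),
         latents = z, cmNoiseFree = cmMean)
  })
}

#' Generate one synthetic bioreactor run
#'
#' @param config A [syntheticConfig()].
#' @param runSeed Integer seed for this run's random draws.
#' @param latents Named numeric vector of standard-normal latents for the
#'   continuous planted channels (see [supportedPlantedFeatures()]); the IWP2
#'   latent is derived from the metadata draw. Missing names default to
#'   fresh draws.
#' @param runId Optional run identifier.
#' @return A [BioreactorRun].
#' @export
generateRun <- function(config, runSeed, latents = NULL, runId = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  cont <- setdiff(.PLANTED_CHANNELS, "meta.iwp2_time")
  full <- .withSeed(.childSeed(runSeed, 1L),
                    structure(stats::rnorm(length(cont)), names = cont))
  if (!is.null(latents)) full[names(latents)] <- latents
  .generateRunFull(config, runSeed, full, runId = runId)$run
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws `nRuns` runs reproducibly from the config seed and returns them
#' together with the generative ground truth (per-run latents, the noise-free
#' CM content and the planted effects), enabling recovery tests of the
#' feature-selection and modelling stages.
#'
#' @param config A [syntheticConfig()].
#' @return List with elements `runs` (list of [BioreactorRun]) and
#'   `groundTruth` (class `GroundTruth`).
#' @examples
#' cohort <- generateCohort(syntheticConfig(nRuns = 3, seed = 11))
#' length(cohort$runs)
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  n <- config$nRuns
  cont <- setdiff(.PLANTED_CHANNELS, "meta.iwp2_time")
  .withSeed(config$seed, {
    runSeeds <- sample.int(.Machine$integer.max - 1L, n)
    zc <- matrix(stats::rnorm(n * length(cont)), n, length(cont),
                 dimnames = list(NULL, cont))
    runs <- vector("list", n)
    latents <- matrix(NA_real_, n, length(.PLANTED_CHANNELS),
                      dimnames = list(NULL, .PLANTED_CHANNELS))
    cmFree <- numeric(n)
    for (i in seq_len(n)) {
      full <- .generateRunFull(config, runSeeds[i], zc[i, ],
                               runId = sprintf("run%03d", i))
      runs[[i]] <- full$run
      latents[i, ] <- full$latents[.PLANTED_CHANNELS]
      cmFree[i] <- full$cmNoiseFree
    }
    gt <- list(latents = latents, cmNoiseFree = cmFree,
               plantedEffects = config$plantedEffects,
               beta0 = .calibrateIntercept(config),
               runIds = vapply(runs, runId, character(1)))
    class(gt) <- "GroundTruth"
    list(runs = runs, groundTruth = gt)
  })
}

#' Tabulate the generative ground truth
#'
#' @param gt The `groundTruth` element of [generateCohort()].
#' @return `data.frame` with one row per planted effect: the feature, its
#'   coefficient (echoed exactly from the config) and the realised latent
#'   mean/SD across the cohort.
#' @export
describeGroundTruth <- function(gt) {
  stopifnot(inherits(gt, "GroundTruth"))
  pe <- gt$plantedEffects
  if (!nrow(pe))
    return(data.frame(feature = character(0), beta = numeric(0),
                      latentMean = numeric(0), latentSd = numeric(0)))
  data.frame(
    feature = pe$feature,
    beta = pe$beta,
    latentMean = colMeans(gt$latents[, pe$feature, drop = FALSE]),
    latentSd = apply(gt$latents[, pe$feature, drop = FALSE], 2L, stats::sd),
    row.names = NULL, stringsAsFactors = FALSE)
}
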
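#' Cohort specification
#'
#' Builds the full specification of a synthetic study cohort. Defaults mirror
#' the emulated clinical study: 41 control and 46 dyslexic adolescents, the
#' standard vergence and saccade protocols (40 trials each), a 150-word
#' meaningful text, and a dyslexic group whose latencies are 40 ms longer,
#' whose movement velocities are 20% slower, whose post-movement drift is
#' doubled and whose reading-regression rate is doubled relative to controls.
#' Reading speed is generated from a linear model on five planted true
#' subject traits (vergence latency, saccade latency, velocity scale,
#' regression probability, fixation duration), standardized across the
#' cohort, with Gaussian noise calibrated so the model explains `targetR2`
#' (default 0.5) of the speed variance.
#'
#' @param nControl,nDyslexic subjects per group.
#' @param vergenceParams,saccadeParams,readingParams control-group kinematics.
#' @param groupOffsets list: `latencyAddMs` (added to both latency means),
#'   `velocityMul` (multiplies main-sequence slopes), `driftMul` (multiplies
#'   drift amplitudes), `regressionMul` (multiplies the regression
#'   probability) for the dyslexic group.
#' @param subjectSD list of between-subject trait SDs: `latencyMs`,
#'   `velocityScale` (relative), `drift` (relative), `regressionProb`
#'   (relative), `fixationMs`.
#' @param speedModel list: `intercept` (words/min), `coefficients` (named,
#'   words/min per SD of each trait; names among `vergenceLatency`,
#'   `saccadeLatency`, `velocityScale`, `regressionProb`, `fixationMean`),
#'   and either `noiseSD` (words/min) or `targetR2` (the fraction of speed
#'   variance the linear part explains; noiseSD is then derived from the
#'   realized signal SD).
#' @param vergenceProtocol,saccadeProtocol stimulus protocols.
#' @param readingWords words in the reading text.
#' @param seed master seed; per-subject substreams are derived by counter.
#' @return a [CohortSpec].
#' @export
cohortSpec <- function(nControl = 41, nDyslexic = 46,
                       vergenceParams = vergenceKinematics(),
                       saccadeParams = saccadeKinematics(),
                       readingParams = readingKinematics(),
                       groupOffsets = list(latencyAddMs = 40,
                                           velocityMul = 0.8,
                                           driftMul = 2,
                                           regressionMul = 2),
                       subjectSD = list(latencyMs = 25,
                                        velocityScale = 0.10,
                                        drift = 0.30,
                                        regressionProb = 0.25,
                                        fixationMs = 25),
                       speedModel = list(
                         intercept = 120,
                         coefficients = c(vergenceLatency = -6,
                                          saccadeLatency = -6,
                                          velocityScale = 6,
                                          regressionProb = -6,
                                          fixationMean = -6),
                         targetR2 = 0.5),
                       vergenceProtocol = binoculaR::vergenceProtocol(),
                       saccadeProtocol = binoculaR::saccadeProtocol(),
                       readingWords = 150, seed = 1L) {
  new("CohortSpec", nControl = as.integer(nControl),
      nDyslexic = as.integer(nDyslexic),
      vergenceParams = vergenceParams, saccadeParams = saccadeParams,
      readingParams = readingParams, groupOffsets = groupOffsets,
      subjectSD = subjectSD, speedModel = speedModel,
      vergenceProtocol = vergenceProtocol, saccadeProtocol = saccadeProtocol,
      readingWords = as.integer(readingWords), seed = as.integer(seed))
}

# Map from planted trait names to regular expressions matching the measured
# feature columns that carry the corresponding signal.
plantedFeatureMap <- function() {
  list(
    vergenceLatency = "^(convergence|divergence)\\.latency\\.mean$",
    saccadeLatency = "^(saccadeLeft|saccadeRight)\\.latency\\.mean$",
    velocityScale = "\\.(averageVelocity|peakVelocity)\\.mean$",
    regressionProb = "^reading\\.pctRegressive\\.value$",
    fixationMean = "^reading\\.fixationDuration\\.mean$"
  )
}

.truncNorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- rnorm(n, mean, sd)
  pmin(pmax(x, lower), upper)
}

#' Generate a synthetic cohort
#'
#' Draws per-subject true traits (group parameters plus between-subject
#' variability), simulates each subject's vergence test, saccade test and
#' reading trace from a subject-specific seed derived from the master seed by
#' counter, and generates reading speed from the configured linear model on
#' the standardized true traits. Deterministic given the specification.
#'
#' @param spec a [CohortSpec].
#' @param sampleRate Hz.
#' @return an [OculoCohort].
#' @export
generateCohort <- function(spec, sampleRate = 200) {
  validObject(spec)
  nC <- spec@nControl; nD <- spec@nDyslexic
  n <- nC + nD
  group <- c(rep("control", nC), rep("dyslexic", nD))
  off <- spec@groupOffsets
  ssd <- spec@subjectSD
  latAdd <- ifelse(group == "dyslexic", off$latencyAddMs, 0)
  velMul <- ifelse(group == "dyslexic", off$velocityMul, 1)
  driMul <- ifelse(group == "dyslexic", off$driftMul, 1)
  regMul <- ifelse(group == "dyslexic", off$regressionMul, 1)

  traits <- withSeed(substreamSeed(spec@seed, 0), data.frame(
    subject = sprintf("S%03d", seq_len(n)),
    group = group,
    vergenceLatency = .truncNorm(n, spec@vergenceParams@latencyMean + latAdd,
                                 ssd$latencyMs, lower = 80),
    saccadeLatency = .truncNorm(n, spec@saccadeParams@latencyMean + latAdd,
                                ssd$latencyMs, lower = 80),
    velocityScale = .truncNorm(n, velMul, ssd$velocityScale * velMul,
                               lower = 0.3),
    driftScale = .truncNorm(n, driMul, ssd$drift * driMul, lower = 0.05),
    regressionProb = .truncNorm(
      n, spec@readingParams@regressionProb * regMul,
      ssd$regressionProb * spec@readingParams@regressionProb * regMul,
      lower = 0.005, upper = 0.9),
    fixationMean = .truncNorm(n, spec@readingParams@fixationMean,
                              ssd$fixationMs, lower = 80)
  ))

  sm <- spec@speedModel
  beta <- sm$coefficients
  zcols <- intersect(names(beta), names(traits))
  signal <- rep(0, n)
  for (nm in zcols) {
    x <- traits[[nm]]
    s <- sd(x)
    z <- if (s > 0) (x - mean(x)) / s else rep(0, n)
    signal <- signal + beta[[nm]] * z
  }
  noiseSD <- if (!is.null(sm$noiseSD)) sm$noiseSD else {
    r2 <- if (!is.null(sm$targetR2)) sm$targetR2 else 0.5
    if (sd(signal) == 0 || r2 <= 0) 0 else sd(signal) * sqrt((1 - r2) / r2)
  }
  speedNoise <- withSeed(substreamSeed(spec@seed, 1),
                         if (noiseSD > 0) rnorm(n, 0, noiseSD) else rep(0, n))
  speed <- pmax(sm$intercept + signal + speedNoise, 10)

  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    si <- substreamSeed(spec@seed, i + 1)
    vp <- spec@vergenceParams
    vp@latencyMean <- traits$vergenceLatency[i]
    vp@peakVelocityScale <- vp@peakVelocityScale * traits$velocityScale[i]
    vp@driftLeft <- vp@driftLeft * traits$driftScale[i]
    vp@driftRight <- vp@driftRight * traits$driftScale[i]
    sp <- spec@saccadeParams
    sp@latencyMean <- traits$saccadeLatency[i]
    sp@peakVelocityScale <- sp@peakVelocityScale * traits$velocityScale[i]
    sp@driftLeft <- sp@driftLeft * traits$driftScale[i]
    sp@driftRight <- sp@driftRight * traits$driftScale[i]
    rp <- spec@readingParams
    rp@regressionProb <- traits$regressionProb[i]
    rp@fixationMean <- traits$fixationMean[i]
    rp@driftLeft <- rp@driftLeft * traits$driftScale[i]
    rp@driftRight <- rp@driftRight * traits$driftScale[i]
    verg <- generateTestRecording(spec@vergenceProtocol, vp, sampleRate,
                                  seed = substreamSeed(si, 1))
    sacc <- generateTestRecording(spec@saccadeProtocol, sp, sampleRate,
                                  seed = substreamSeed(si, 2))
    read <- generateReadingTrace(spec@readingWords, rp, sampleRate,
                                 seed = substreamSeed(si, 3))
    subjects[[i]] <- list(
      subject = traits$subject[i], group = group[i],
      readingSpeed = speed[i],
      traces = list(vergence = verg$trace, saccade = sacc$trace,
                    reading = read$trace),
      truth = list(vergence = verg$truth, saccade = sacc$truth,
                   reading = read$truth)
    )
  }
  traits$readingSpeed <- speed
  new("OculoCohort", subjects = subjects, traits = traits, spec = spec,
      planted = plantedFeatureMap()[zcols])
}
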
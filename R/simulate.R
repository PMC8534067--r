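#' Kinematic parameter constructors
#'
#' Defaults describe a typical adolescent control subject. Vergence responses
#' to disparity steps are simulated with a brisk phasic component
#' (main-sequence slope 10 (deg/s)/deg, i.e. ~157 ms duration and ~85 deg/s
#' peak velocity for the ~8.5 degree convergence step); saccades follow a
#' 20 (deg/s)/deg main sequence (~400 deg/s peak, ~79 ms duration at 20
#' degrees). Post-movement drift is exponential per eye; its left-minus-right
#' component is the disconjugate drift the extractor measures over 80 and
#' 160 ms windows.
#'
#' @param latencyMean,latencySD latency distribution (ms).
#' @param peakVelocityScale main-sequence slope, (deg/s)/deg.
#' @param driftLeft,driftRight asymptotic post-movement drift per eye (deg).
#' @param driftTau drift time constant (ms).
#' @param disconjugacy left-minus-right saccade amplitude difference (deg).
#' @param noiseSD white position noise SD (deg).
#' @param blinkProb per-trial blink-artifact probability.
#' @return a [KinematicParams] object.
#' @export
vergenceKinematics <- function(latencyMean = 200, latencySD = 30,
                               peakVelocityScale = 10,
                               driftLeft = 0.20, driftRight = 0.10,
                               driftTau = 100, disconjugacy = 0,
                               noiseSD = 0.05, blinkProb = 0.01) {
  new("KinematicParams", latencyMean = latencyMean, latencySD = latencySD,
      peakVelocityScale = peakVelocityScale, driftLeft = driftLeft,
      driftRight = driftRight, driftTau = driftTau,
      disconjugacy = disconjugacy, noiseSD = noiseSD, blinkProb = blinkProb)
}

#' @rdname vergenceKinematics
#' @export
saccadeKinematics <- function(latencyMean = 180, latencySD = 25,
                              peakVelocityScale = 20,
                              driftLeft = 0.30, driftRight = 0.15,
                              driftTau = 80, disconjugacy = 0.20,
                              noiseSD = 0.05, blinkProb = 0.07) {
  new("KinematicParams", latencyMean = latencyMean, latencySD = latencySD,
      peakVelocityScale = peakVelocityScale, driftLeft = driftLeft,
      driftRight = driftRight, driftTau = driftTau,
      disconjugacy = disconjugacy, noiseSD = noiseSD, blinkProb = blinkProb)
}

#' Reading parameter constructor
#'
#' Defaults: 250 ms mean fixations (gamma, shape 4), 2 degree progressive and
#' -1.5 degree regressive saccades, 15% regression probability, 10 words per
#' line with a leftward return sweep at each line break.
#'
#' @param fixationMean,fixationShape gamma fixation-duration distribution:
#'   mean (ms) and shape.
#' @param progressiveAmplitude,regressiveAmplitude saccade amplitudes (deg).
#' @param regressionProb per-word regression probability.
#' @param wordsPerLine words per text line.
#' @param peakVelocityScale main-sequence slope for reading saccades.
#' @param driftLeft,driftRight,driftTau per-fixation disconjugate drift model.
#' @param noiseSD position noise SD (deg).
#' @return a [ReadingParams] object.
#' @export
readingKinematics <- function(fixationMean = 250, fixationShape = 4,
                              progressiveAmplitude = 2,
                              regressiveAmplitude = -1.5,
                              regressionProb = 0.15, wordsPerLine = 10,
                              peakVelocityScale = 50,
                              driftLeft = 0.10, driftRight = 0.05,
                              driftTau = 80, noiseSD = 0.05) {
  new("ReadingParams", fixationMean = fixationMean,
      fixationShape = fixationShape,
      progressiveAmplitude = progressiveAmplitude,
      regressiveAmplitude = regressiveAmplitude,
      regressionProb = regressionProb, wordsPerLine = wordsPerLine,
      peakVelocityScale = peakVelocityScale, driftLeft = driftLeft,
      driftRight = driftRight, driftTau = driftTau, noiseSD = noiseSD)
}

# Blink artifact: a 100 ms large-amplitude excursion replacing the signal on
# both eyes, emulating lid occlusion of the pupil image.
.blinkAmplitude <- 45
.blinkDuration <- 0.100

.applyBlink <- function(time, left, right, onset) {
  idx <- time >= onset & time < onset + .blinkDuration
  left[idx] <- left[idx] + .blinkAmplitude
  right[idx] <- right[idx] + .blinkAmplitude
  list(left = left, right = right)
}

#' Generate one vergence trial
#'
#' Simulates a single convergence or divergence trial: binocular fixation at
#' the protocol's fixation vergence angle, then after a drawn latency a
#' raised-cosine vergence step toward the target angle, followed by
#' exponential post-movement drift with a disconjugate component, plus white
#' position noise. Uses the current RNG state.
#'
#' @param kind "convergence" or "divergence".
#' @param fixationMs fixation duration of this trial (ms).
#' @param params a [KinematicParams].
#' @param protocol a vergence [StimulusProtocol].
#' @param sampleRate sampling rate (Hz).
#' @return list with elements `time`, `left`, `right` (the trial segment,
#'   time starting at 0), `targetOnset` (s) and `truth` (one-row data.frame
#'   of drawn ground-truth values).
#' @export
generateVergenceTrial <- function(kind, fixationMs, params,
                                  protocol = vergenceProtocol(),
                                  sampleRate = 200) {
  stopIfNot(kind %in% c("convergence", "divergence"),
            "kind must be 'convergence' or 'divergence'")
  validObject(params)
  v0 <- vergenceAngle(protocol@fixationDistance, protocol@interocular)
  vt <- vergenceAngle(
    if (kind == "convergence") protocol@convergenceDistance
    else protocol@divergenceDistance,
    protocol@interocular)
  amp <- vt - v0
  latency <- max(rnorm(1, params@latencyMean, params@latencySD), 50) / 1000
  dur <- profileDuration(params@peakVelocityScale)
  targetOnset <- fixationMs / 1000
  total <- (fixationMs + protocol@targetDuration) / 1000
  n <- floor(total * sampleRate)
  time <- seq_len(n) / sampleRate - 1 / sampleRate
  tMove <- targetOnset + latency
  ramp <- raisedCosine((time - tMove) / dur)
  g <- driftShape(time - (tMove + dur), params@driftTau / 1000)
  noiseL <- if (params@noiseSD > 0) rnorm(n, 0, params@noiseSD) else 0
  noiseR <- if (params@noiseSD > 0) rnorm(n, 0, params@noiseSD) else 0
  left <- v0 / 2 + (amp / 2) * ramp + params@driftLeft * g + noiseL
  right <- -v0 / 2 - (amp / 2) * ramp + params@driftRight * g + noiseR
  blink <- runif(1) < params@blinkProb
  if (blink) {
    b <- .applyBlink(time, left, right,
                     runif(1, targetOnset, targetOnset + 1.0))
    left <- b$left; right <- b$right
  }
  truth <- data.frame(
    kind = kind, targetOnset = targetOnset, latency = latency * 1000,
    amplitude = amp, duration = dur * 1000,
    peakVelocity = pi * abs(amp) / (2 * dur),
    driftLeft = params@driftLeft, driftRight = params@driftRight,
    driftTau = params@driftTau, blink = blink,
    moveOnset = tMove, moveOffset = tMove + dur
  )
  list(time = time, left = left, right = right, targetOnset = targetOnset,
       truth = truth)
}

#' Generate one saccade trial
#'
#' Simulates a single 20-degree (by default) leftward or rightward saccade:
#' a conjugate raised-cosine step whose peak velocity follows the configured
#' main sequence, with the configured left-minus-right amplitude difference
#' (disconjugacy) and per-eye post-saccadic drift, plus noise. Uses the
#' current RNG state.
#'
#' @param kind "saccadeLeft" or "saccadeRight".
#' @inheritParams generateVergenceTrial
#' @return as [generateVergenceTrial()].
#' @export
generateSaccadeTrial <- function(kind, fixationMs, params,
                                 protocol = saccadeProtocol(),
                                 sampleRate = 200) {
  stopIfNot(kind %in% c("saccadeLeft", "saccadeRight"),
            "kind must be 'saccadeLeft' or 'saccadeRight'")
  validObject(params)
  v0 <- vergenceAngle(protocol@fixationDistance, protocol@interocular)
  amp <- if (kind == "saccadeRight") protocol@eccentricity else
    -protocol@eccentricity
  latency <- max(rnorm(1, params@latencyMean, params@latencySD), 50) / 1000
  dur <- profileDuration(params@peakVelocityScale)
  targetOnset <- fixationMs / 1000
  total <- (fixationMs + protocol@targetDuration) / 1000
  n <- floor(total * sampleRate)
  time <- seq_len(n) / sampleRate - 1 / sampleRate
  tMove <- targetOnset + latency
  ramp <- raisedCosine((time - tMove) / dur)
  g <- driftShape(time - (tMove + dur), params@driftTau / 1000)
  noiseL <- if (params@noiseSD > 0) rnorm(n, 0, params@noiseSD) else 0
  noiseR <- if (params@noiseSD > 0) rnorm(n, 0, params@noiseSD) else 0
  left <- v0 / 2 + (amp + params@disconjugacy / 2) * ramp +
    params@driftLeft * g + noiseL
  right <- -v0 / 2 + (amp - params@disconjugacy / 2) * ramp +
    params@driftRight * g + noiseR
  blink <- runif(1) < params@blinkProb
  if (blink) {
    b <- .applyBlink(time, left, right,
                     runif(1, targetOnset, targetOnset + 1.0))
    left <- b$left; right <- b$right
  }
  truth <- data.frame(
    kind = kind, targetOnset = targetOnset, latency = latency * 1000,
    amplitude = amp, duration = dur * 1000,
    peakVelocity = pi * abs(amp) / (2 * dur),
    driftLeft = params@driftLeft, driftRight = params@driftRight,
    driftTau = params@driftTau, blink = blink,
    moveOnset = tMove, moveOffset = tMove + dur,
    disconjugacy = params@disconjugacy
  )
  list(time = time, left = left, right = right, targetOnset = targetOnset,
       truth = truth)
}

#' Generate a full test recording for one subject
#'
#' Draws the protocol's interleaved trial sequence and concatenates the
#' per-trial segments into one continuous [BinocularTrace] with a target-onset
#' event per trial.
#'
#' @param protocol a [StimulusProtocol].
#' @param params a [KinematicParams].
#' @param sampleRate Hz.
#' @param seed optional integer seed (uses the current RNG state when NULL).
#' @return list `trace` ([BinocularTrace]) and `truth` (data.frame, one row
#'   per trial).
#' @export
generateTestRecording <- function(protocol, params, sampleRate = 200,
                                  seed = NULL) {
  withSeed(seed, {
    trials <- drawTrials(protocol)
    gen <- if (protocol@kind == "vergence") generateVergenceTrial else
      generateSaccadeTrial
    segs <- lapply(seq_len(nrow(trials)), function(i)
      gen(trials$kind[i], trials$fixationMs[i], params, protocol, sampleRate))
    offsets <- cumsum(c(0, vapply(segs, function(s)
      length(s$time) / sampleRate, numeric(1))))[seq_along(segs)]
    time <- unlist(lapply(seq_along(segs), function(i)
      segs[[i]]$time + offsets[i]))
    left <- unlist(lapply(segs, `[[`, "left"))
    right <- unlist(lapply(segs, `[[`, "right"))
    truth <- do.call(rbind, lapply(segs, `[[`, "truth"))
    truth$trialStart <- offsets
    truth$targetOnset <- truth$targetOnset + offsets
    truth$moveOnset <- truth$moveOnset + offsets
    truth$moveOffset <- truth$moveOffset + offsets
    events <- data.frame(onset = truth$targetOnset, kind = truth$kind)
    trace <- new("BinocularTrace", time = time, left = left, right = right,
                 sampleRate = sampleRate, events = events)
    list(trace = trace, truth = truth)
  })
}

#' Generate a reading trace
#'
#' Simulates left-to-right reading of `words` words: gamma-distributed
#' fixations alternating with progressive saccades, regressive saccades
#' inserted with the configured probability, and a large leftward return
#' sweep at each line break. Each fixation carries per-eye exponential drift
#' (the disconjugate component the extractor measures). The returned reading
#' speed is `words / (trace duration in minutes)`.
#'
#' @param words number of words (>= 1).
#' @param params a [ReadingParams].
#' @param sampleRate Hz.
#' @param seed optional seed.
#' @param fixationDistance,interocular geometry for the baseline vergence
#'   angle (m).
#' @return list `trace` ([BinocularTrace] with word-onset events),
#'   `truth` (list: per-fixation durations, saccade table, counts, speed),
#'   and `speed` (words/min).
#' @export
generateReadingTrace <- function(words, params = readingKinematics(),
                                 sampleRate = 200, seed = NULL,
                                 fixationDistance = 0.40,
                                 interocular = 0.060) {
  stopIfNot(words >= 1, "words must be >= 1")
  validObject(params)
  withSeed(seed, {
    v0 <- vergenceAngle(fixationDistance, interocular)
    fixDur <- rgamma(words, shape = params@fixationShape,
                     scale = params@fixationMean / params@fixationShape) / 1000
    # plan the saccade sequence (between consecutive words)
    pos <- 0
    sacc <- list()
    conjSeg <- list()   # per segment: c(start, end, posStart, amp) or fixation
    cursor <- 0
    capVel <- 500
    for (i in seq_len(words)) {
      conjSeg[[length(conjSeg) + 1]] <-
        list(type = "fix", start = cursor, end = cursor + fixDur[i],
             pos = pos)
      cursor <- cursor + fixDur[i]
      if (i == words) break
      if (i %% params@wordsPerLine == 0) {
        amp <- -pos; type <- "sweep"
      } else if (runif(1) < params@regressionProb) {
        amp <- params@regressiveAmplitude; type <- "regressive"
      } else {
        amp <- params@progressiveAmplitude; type <- "progressive"
      }
      vp <- min(params@peakVelocityScale * abs(amp), capVel)
      dur <- pi * abs(amp) / (2 * vp)
      sacc[[length(sacc) + 1]] <-
        data.frame(onset = cursor, duration = dur, amplitude = amp,
                   peakVelocity = vp, type = type)
      conjSeg[[length(conjSeg) + 1]] <-
        list(type = "sacc", start = cursor, end = cursor + dur, pos = pos,
             amp = amp)
      cursor <- cursor + dur
      pos <- pos + amp
    }
    total <- cursor
    n <- floor(total * sampleRate)
    time <- seq_len(n) / sampleRate - 1 / sampleRate
    conj <- numeric(n)
    dL <- numeric(n); dR <- numeric(n)
    tau <- params@driftTau / 1000
    for (seg in conjSeg) {
      idx <- which(time >= seg$start & time < seg$end)
      if (!length(idx)) next
      if (seg$type == "fix") {
        conj[idx] <- seg$pos
        g <- driftShape(time[idx] - seg$start, tau)
        dL[idx] <- params@driftLeft * g
        dR[idx] <- params@driftRight * g
      } else {
        conj[idx] <- seg$pos +
          seg$amp * raisedCosine((time[idx] - seg$start) /
                                   (seg$end - seg$start))
      }
    }
    after <- time >= total
    noiseL <- if (params@noiseSD > 0) rnorm(n, 0, params@noiseSD) else 0
    noiseR <- if (params@noiseSD > 0) rnorm(n, 0, params@noiseSD) else 0
    left <- conj + v0 / 2 + dL + noiseL
    right <- conj - v0 / 2 + dR + noiseR
    saccTable <- if (length(sacc)) do.call(rbind, sacc) else
      data.frame(onset = numeric(0), duration = numeric(0),
                 amplitude = numeric(0), peakVelocity = numeric(0),
                 type = character(0))
    speed <- words / (total / 60)
    trace <- new("BinocularTrace", time = time, left = left, right = right,
                 sampleRate = sampleRate,
                 events = data.frame(onset = 0, kind = "readingStart"))
    truth <- list(fixationDurations = fixDur * 1000, saccades = saccTable,
                  nProgressive = sum(saccTable$type == "progressive"),
                  nRegressive = sum(saccTable$type == "regressive"),
                  nSweeps = sum(saccTable$type == "sweep"),
                  words = words, duration = total, speed = speed)
    list(trace = trace, truth = truth, speed = speed)
  })
}
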
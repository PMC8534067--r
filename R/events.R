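#' Extraction configuration
#'
#' Parameters of the velocity-threshold event analysis. Vergence movements
#' are bounded by 5 deg/s crossings of the vergence-channel velocity;
#' saccades are located on the conjugate channel via a practical 40 deg/s
#' floor and refined to the first/last crossings of 10% of the candidate's
#' peak velocity (for a typical 400 deg/s, 20-degree saccade the two rules
#' coincide). Post-movement amplitude changes are measured over 80 and
#' 160 ms windows from movement offset. Position series are smoothed with a
#' Savitzky-Golay filter (order 2, 5 samples by default: peak-preserving)
#' before 2-point central differencing at the sampling rate.
#'
#' @param vergenceThreshold vergence velocity threshold (deg/s).
#' @param saccadeFloor practical saccade velocity floor (deg/s).
#' @param peakFraction onset/offset refinement fraction of peak velocity.
#' @param readingFloor velocity floor for small reading saccades (deg/s).
#' @param driftWindow1,driftWindow2 post-movement windows (ms).
#' @param smoothWindow Savitzky-Golay window length (odd, samples); 1
#'   disables smoothing.
#' @param smoothOrder Savitzky-Golay polynomial order.
#' @param positionBound plausibility bound (deg); REMOBI trials containing
#'   samples beyond it (e.g. blink excursions) are flagged invalid.
#' @param velocityBound plausibility bound (deg/s) applied to each eye's
#'   velocity within a trial; lid-artifact edges exceed it by an order of
#'   magnitude while genuine saccades stay well below.
#' @param sweepAmplitude leftward amplitude (deg) beyond which a reading
#'   saccade is treated as a line-return sweep, not a regression.
#' @return a list of class `ExtractionConfig`.
#' @export
extractionConfig <- function(vergenceThreshold = 5, saccadeFloor = 40,
                             peakFraction = 0.10, readingFloor = 30,
                             driftWindow1 = 80, driftWindow2 = 160,
                             smoothWindow = 5, smoothOrder = 2,
                             positionBound = 40, velocityBound = 1500,
                             sweepAmplitude = 5) {
  stopIfNot(vergenceThreshold > 0 && saccadeFloor > 0 && readingFloor > 0,
            "velocity thresholds must be > 0")
  stopIfNot(driftWindow1 < driftWindow2,
            "driftWindow1 must be smaller than driftWindow2")
  stopIfNot(smoothWindow >= 1 && smoothWindow %% 2 == 1,
            "smoothWindow must be odd")
  kernel <- NULL
  if (smoothWindow > 1) {
    stopIfNot(smoothOrder < smoothWindow, "smoothOrder must be < smoothWindow")
    sg <- signal::sgolay(p = smoothOrder, n = smoothWindow)
    kernel <- as.numeric(sg[(smoothWindow + 1) / 2, ])
  }
  structure(list(
    vergenceThreshold = vergenceThreshold, saccadeFloor = saccadeFloor,
    peakFraction = peakFraction, readingFloor = readingFloor,
    driftWindow1 = driftWindow1, driftWindow2 = driftWindow2,
    smoothWindow = smoothWindow, smoothOrder = smoothOrder,
    positionBound = positionBound, velocityBound = velocityBound,
    sweepAmplitude = sweepAmplitude,
    sgKernel = kernel
  ), class = "ExtractionConfig")
}

#' Derive vergence and conjugate channels
#'
#' Vergence is the left-minus-right eye position difference (positive =
#' convergence); the conjugate signal is the two-eye average. The two eyes
#' are exactly reconstructible as `conjugate + vergence / 2` (left) and
#' `conjugate - vergence / 2` (right).
#'
#' @param trace a [BinocularTrace].
#' @return list with numeric vectors `vergence` and `conjugate`,
#'   sample-aligned with the trace.
#' @export
deriveChannels <- function(trace) {
  validObject(trace)
  list(vergence = trace@left - trace@right,
       conjugate = (trace@left + trace@right) / 2)
}

.smoothSeries <- function(x, config) {
  if (is.null(config$sgKernel)) return(x)
  sm <- as.numeric(stats::filter(x, config$sgKernel, sides = 2))
  na <- is.na(sm)
  sm[na] <- x[na]
  sm
}

#' Velocity of a position series
#'
#' Optional Savitzky-Golay smoothing followed by 2-point central differences
#' (one-sided at the endpoints); same length as the input.
#'
#' @param x position series (deg).
#' @param sampleRate Hz.
#' @param config an [extractionConfig()].
#' @return velocity series (deg/s).
#' @export
traceVelocity <- function(x, sampleRate, config = extractionConfig()) {
  stopIfNot(length(x) >= 3, "series must have at least 3 samples")
  xs <- .smoothSeries(x, config)
  n <- length(xs)
  v <- numeric(n)
  v[2:(n - 1)] <- (xs[3:n] - xs[1:(n - 2)]) * sampleRate / 2
  v[1] <- (xs[2] - xs[1]) * sampleRate
  v[n] <- (xs[n] - xs[n - 1]) * sampleRate
  v
}

# Linear interpolation of the time at which |v| crosses `thr` between
# samples i (below) and j (above), or the reverse.
.crossTime <- function(time, av, i, j, thr) {
  if (av[j] == av[i]) return(time[j])
  time[i] + (thr - av[i]) / (av[j] - av[i]) * (time[j] - time[i])
}

.seriesAt <- function(time, x, t) approx(time, x, xout = t, rule = 2)$y

#' Detect the initial vergence movement in a window
#'
#' Onset is the first crossing of the vergence velocity above the threshold
#' after target onset; offset is the first subsequent drop below it.
#' Crossing times are refined by linear interpolation between the straddling
#' samples. Returns `NULL` when no crossing occurs.
#'
#' @param position vergence position series (deg).
#' @param time sample times (s).
#' @param window two-element window (s), typically target onset to target
#'   offset.
#' @param config an [extractionConfig()].
#' @param sampleRate Hz (inferred from `time` when NULL).
#' @param velocity optional precomputed velocity series.
#' @return a [MovementSegment] or `NULL`.
#' @export
detectVergenceMovement <- function(position, time, window,
                                   config = extractionConfig(),
                                   sampleRate = NULL, velocity = NULL) {
  if (is.null(sampleRate)) sampleRate <- 1 / mean(diff(time))
  if (is.null(velocity)) velocity <- traceVelocity(position, sampleRate, config)
  idx <- which(time >= window[1] & time <= window[2])
  if (length(idx) < 3) return(NULL)
  av <- abs(velocity[idx])
  thr <- config$vergenceThreshold
  above <- av >= thr
  on <- which(above)[1]
  if (is.na(on)) return(NULL)
  onT <- if (on == 1) time[idx[1]] else
    .crossTime(time[idx], av, on - 1, on, thr)
  offCand <- which(!above & seq_along(above) > on)[1]
  offT <- if (is.na(offCand)) time[idx[length(idx)]] else
    .crossTime(time[idx], av, offCand - 1, offCand, thr)
  seg <- idx[time[idx] >= onT & time[idx] <= offT]
  peak <- if (length(seg)) max(abs(velocity[seg])) else thr
  amp <- .seriesAt(time, position, offT) - .seriesAt(time, position, onT)
  new("MovementSegment", channel = "vergence", onset = onT, offset = offT,
      amplitude = amp, peakVelocity = peak)
}

#' Detect a saccade in a window
#'
#' The candidate is the first contiguous run of samples whose conjugate
#' velocity magnitude exceeds the practical floor (40 deg/s by default);
#' onset and offset are then refined outward/inward to the first and last
#' crossings of 10% of the candidate's peak velocity, interpolated between
#' samples. Returns `NULL` when no sample reaches the floor.
#'
#' @param position conjugate position series (deg) (or a single eye's series
#'   when measuring per-eye amplitudes).
#' @inheritParams detectVergenceMovement
#' @param floor velocity floor (deg/s); defaults to `config$saccadeFloor`.
#' @return a [MovementSegment] or `NULL`.
#' @export
detectSaccade <- function(position, time, window,
                          config = extractionConfig(), sampleRate = NULL,
                          velocity = NULL, floor = config$saccadeFloor) {
  if (is.null(sampleRate)) sampleRate <- 1 / mean(diff(time))
  if (is.null(velocity)) velocity <- traceVelocity(position, sampleRate, config)
  idx <- which(time >= window[1] & time <= window[2])
  if (length(idx) < 3) return(NULL)
  av <- abs(velocity[idx])
  hot <- av >= floor
  if (!any(hot)) return(NULL)
  first <- which(hot)[1]
  runEnd <- first
  while (runEnd < length(hot) && hot[runEnd + 1]) runEnd <- runEnd + 1
  peakRel <- which.max(av[first:runEnd]) + first - 1
  peak <- av[peakRel]
  thr <- config$peakFraction * peak
  on <- peakRel
  while (on > 1 && av[on - 1] >= thr) on <- on - 1
  onT <- if (on == 1 || av[on - 1] >= thr) time[idx[on]] else
    .crossTime(time[idx], av, on - 1, on, thr)
  off <- peakRel
  while (off < length(av) && av[off + 1] >= thr) off <- off + 1
  offT <- if (off == length(av) || av[off + 1] >= thr) time[idx[off]] else
    .crossTime(time[idx], av, off + 1, off, thr)
  amp <- .seriesAt(time, position, offT) - .seriesAt(time, position, onT)
  new("MovementSegment", channel = "conjugate", onset = onT, offset = offT,
      amplitude = amp, peakVelocity = peak)
}

#' Per-trial descriptors from a detected movement
#'
#' Computes the descriptor set of one trial: latency (movement onset minus
#' target onset), the phasic amplitude between the two velocity-threshold
#' crossings, the amplitude change over the subsequent 80 and 160 ms, the
#' total amplitude (phasic + 160 ms component) and total duration (phasic +
#' 160 ms), peak velocity, average velocity (|total amplitude| / total
#' duration), the saccade disconjugacy (left-minus-right amplitude over the
#' conjugate-defined interval) and the disconjugate drift over the 80 and
#' 160 ms windows after movement offset.
#'
#' @param trace a [BinocularTrace].
#' @param segment a [MovementSegment] (or `NULL` for an invalid trial).
#' @param targetOnset target onset time (s).
#' @param config an [extractionConfig()].
#' @param test "vergence" or "saccade" (selects the channel for the 80/160 ms
#'   amplitude components).
#' @return one-row data.frame; all descriptor values `NA` with
#'   `valid = FALSE` when `segment` is `NULL`.
#' @export
computeTrialDescriptors <- function(trace, segment, targetOnset,
                                    config = extractionConfig(),
                                    test = c("vergence", "saccade")) {
  test <- match.arg(test)
  empty <- data.frame(
    latency = NA_real_, phasicAmplitude = NA_real_, amp80 = NA_real_,
    amp160 = NA_real_, totalAmplitude = NA_real_, phasicDuration = NA_real_,
    totalDuration = NA_real_, peakVelocity = NA_real_,
    averageVelocity = NA_real_, disconjugacy = NA_real_,
    drift1 = NA_real_, drift2 = NA_real_, valid = FALSE
  )
  if (is.null(segment)) return(empty)
  ch <- deriveChannels(trace)
  chan <- if (test == "vergence") ch$vergence else ch$conjugate
  tm <- trace@time
  w1 <- config$driftWindow1 / 1000
  w2 <- config$driftWindow2 / 1000
  onT <- segment@onset; offT <- segment@offset
  chanAt <- function(t) .seriesAt(tm, chan, t)
  amp80 <- chanAt(offT + w1) - chanAt(offT)
  amp160 <- chanAt(offT + w2) - chanAt(offT)
  phasic <- segment@amplitude
  totalAmp <- phasic + amp160
  phasicDur <- (offT - onT) * 1000
  totalDur <- phasicDur + config$driftWindow2
  lAt <- function(t) .seriesAt(tm, trace@left, t)
  rAt <- function(t) .seriesAt(tm, trace@right, t)
  disc <- (lAt(offT) - lAt(onT)) - (rAt(offT) - rAt(onT))
  drift1 <- (lAt(offT + w1) - lAt(offT)) - (rAt(offT + w1) - rAt(offT))
  drift2 <- (lAt(offT + w2) - lAt(offT)) - (rAt(offT + w2) - rAt(offT))
  data.frame(
    latency = (onT - targetOnset) * 1000,
    phasicAmplitude = phasic, amp80 = amp80, amp160 = amp160,
    totalAmplitude = totalAmp, phasicDuration = phasicDur,
    totalDuration = totalDur, peakVelocity = segment@peakVelocity,
    averageVelocity = abs(totalAmp) / (totalDur / 1000),
    disconjugacy = if (test == "saccade") disc else NA_real_,
    drift1 = drift1, drift2 = drift2, valid = TRUE
  )
}

#' Extract per-trial descriptors for a whole test recording
#'
#' Runs detection and descriptor computation for every target event of a
#' vergence or saccade recording. A trial is flagged invalid (all descriptor
#' values aberrant) when no movement is detected in the target window, when
#' the detected onset falls outside it, or when the trial contains samples
#' beyond the position plausibility bound (blink artifacts).
#'
#' @param trace a [BinocularTrace] with one target event per trial.
#' @param config an [extractionConfig()].
#' @param test "vergence" or "saccade".
#' @param targetDuration search-window length after target onset (s).
#' @return data.frame, one row per trial: `kind`, the descriptors, `valid`.
#' @export
extractTrials <- function(trace, config = extractionConfig(),
                          test = c("vergence", "saccade"),
                          targetDuration = 2) {
  test <- match.arg(test)
  validObject(trace)
  ch <- deriveChannels(trace)
  chan <- if (test == "vergence") ch$vergence else ch$conjugate
  vel <- traceVelocity(chan, trace@sampleRate, config)
  pad <- config$driftWindow2 / 1000 + 0.05
  rows <- lapply(seq_len(nrow(trace@events)), function(i) {
    onset <- trace@events$onset[i]
    window <- c(onset, onset + targetDuration)
    # work on the trial's slice only; descriptor windows never leave it
    i0 <- max(1L, sum(trace@time < window[1]) - 1L)
    i1 <- min(length(trace@time), sum(trace@time <= window[2] + pad) + 1L)
    sl <- i0:i1
    sub <- new("BinocularTrace", time = trace@time[sl],
               left = trace@left[sl], right = trace@right[sl],
               sampleRate = trace@sampleRate,
               events = trace@events[i, , drop = FALSE])
    # plausibility screen stops short of the trial boundary, where the
    # between-trial position reset would masquerade as a velocity artifact
    chk <- sub@time <= window[2] - 4 / sub@sampleRate
    artifact <- any(abs(sub@left[chk]) > config$positionBound |
                      abs(sub@right[chk]) > config$positionBound) ||
      max(abs(traceVelocity(sub@left, sub@sampleRate, config)[chk]),
          abs(traceVelocity(sub@right, sub@sampleRate, config)[chk])) >
        config$velocityBound
    seg <- if (artifact) NULL else if (test == "vergence")
      detectVergenceMovement(chan[sl], sub@time, window, config,
                             trace@sampleRate, vel[sl])
    else detectSaccade(chan[sl], sub@time, window, config,
                       trace@sampleRate, vel[sl])
    row <- computeTrialDescriptors(sub, seg, onset, config, test)
    if (row$valid && (row$latency < 0 || row$latency > targetDuration * 1000))
      row <- computeTrialDescriptors(sub, NULL, onset, config, test)
    row$kind <- trace@events$kind[i]
    row
  })
  out <- do.call(rbind, rows)
  out[, c("kind", setdiff(names(out), "kind"))]
}

#' Reading descriptors from a reading trace
#'
#' Segments the conjugate channel into saccades and fixations by applying the
#' saccade detector sequentially with the (lower) reading velocity floor.
#' Saccades are classified by sign and amplitude: rightward = progressive,
#' leftward smaller than the sweep bound = regressive, larger leftward =
#' line-return sweep (excluded from the regression count). Fixation duration
#' is the interval between one saccade's offset and the next one's onset;
#' per-fixation disconjugate drift is the left-minus-right position change
#' over the first 80 ms of fixation. Per-eye amplitudes and velocities are
#' measured over each progressive saccade's conjugate-defined interval.
#'
#' @param trace a [BinocularTrace].
#' @param config an [extractionConfig()].
#' @return list: `saccades` (table with per-saccade measures and class),
#'   `fixations` (durations, drift), `units` (long data.frame of per-unit
#'   descriptor values), `scalars` (named vector: nProgressive, nRegressive,
#'   pctRegressive), `valid`.
#' @export
computeReadingDescriptors <- function(trace, config = extractionConfig()) {
  validObject(trace)
  ch <- deriveChannels(trace)
  tm <- trace@time
  vel <- traceVelocity(ch$conjugate, trace@sampleRate, config)
  av <- abs(vel)
  hot <- av >= config$readingFloor
  if (!any(hot)) {
    return(list(saccades = NULL, fixations = NULL,
                units = data.frame(descriptor = character(0),
                                   value = numeric(0)),
                scalars = c(nProgressive = NA_real_, nRegressive = NA_real_,
                            pctRegressive = NA_real_),
                valid = FALSE))
  }
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  segs <- lapply(seq_len(nrow(runs)), function(i) {
    a <- runs$start[i]; b <- runs$end[i]
    peakRel <- which.max(av[a:b]) + a - 1
    thr <- config$peakFraction * av[peakRel]
    on <- peakRel
    while (on > 1 && av[on - 1] >= thr) on <- on - 1
    onT <- if (on == 1) tm[on] else .crossTime(tm, av, on - 1, on, thr)
    off <- peakRel
    while (off < length(av) && av[off + 1] >= thr) off <- off + 1
    offT <- if (off == length(av)) tm[off] else
      .crossTime(tm, av, off + 1, off, thr)
    c(onset = onT, offset = offT, peak = av[peakRel])
  })
  sac <- unique(as.data.frame(do.call(rbind, segs)))
  sac <- sac[order(sac$onset), ]
  # merge overlapping refinements of the same physical saccade
  keep <- c(TRUE, diff(sac$onset) > 1e-9)
  sac <- sac[keep, , drop = FALSE]
  conjAt <- function(t) .seriesAt(tm, ch$conjugate, t)
  lAt <- function(t) .seriesAt(tm, trace@left, t)
  rAt <- function(t) .seriesAt(tm, trace@right, t)
  sac$amplitude <- conjAt(sac$offset) - conjAt(sac$onset)
  sac$ampLeft <- lAt(sac$offset) - lAt(sac$onset)
  sac$ampRight <- rAt(sac$offset) - rAt(sac$onset)
  sac$duration <- (sac$offset - sac$onset) * 1000
  sac$class <- ifelse(sac$amplitude > 0, "progressive",
                      ifelse(sac$amplitude > -config$sweepAmplitude,
                             "regressive", "sweep"))
  # per-eye peak velocities over the saccade interval
  velL <- traceVelocity(trace@left, trace@sampleRate, config)
  velR <- traceVelocity(trace@right, trace@sampleRate, config)
  sac$peakLeft <- vapply(seq_len(nrow(sac)), function(i) {
    ii <- tm >= sac$onset[i] & tm <= sac$offset[i]
    if (any(ii)) max(abs(velL[ii])) else NA_real_
  }, numeric(1))
  sac$peakRight <- vapply(seq_len(nrow(sac)), function(i) {
    ii <- tm >= sac$onset[i] & tm <= sac$offset[i]
    if (any(ii)) max(abs(velR[ii])) else NA_real_
  }, numeric(1))
  nSac <- nrow(sac)
  fix <- NULL
  if (nSac >= 2) {
    fs <- sac$offset[-nSac]
    fe <- sac$onset[-1]
    dur <- (fe - fs) * 1000
    w1 <- config$driftWindow1 / 1000
    drift <- ifelse(fe - fs >= w1,
                    (lAt(fs + w1) - lAt(fs)) - (rAt(fs + w1) - rAt(fs)),
                    NA_real_)
    fix <- data.frame(start = fs, end = fe, duration = dur, drift = drift)
  }
  prog <- sac[sac$class == "progressive", , drop = FALSE]
  nProg <- nrow(prog)
  nReg <- sum(sac$class == "regressive")
  pctReg <- if (nProg > 0) 100 * nReg / nProg else NA_real_
  units <- rbind(
    if (!is.null(fix)) data.frame(descriptor = "fixationDuration",
                                  value = fix$duration),
    if (!is.null(fix) && any(!is.na(fix$drift)))
      data.frame(descriptor = "driftDisconjugate",
                 value = fix$drift[!is.na(fix$drift)]),
    if (nProg) data.frame(descriptor = "saccadeAmplitudeLeft",
                          value = prog$ampLeft),
    if (nProg) data.frame(descriptor = "saccadeAmplitudeRight",
                          value = prog$ampRight),
    if (nProg) data.frame(descriptor = "peakVelocityLeft",
                          value = prog$peakLeft),
    if (nProg) data.frame(descriptor = "peakVelocityRight",
                          value = prog$peakRight),
    if (nProg) data.frame(descriptor = "averageVelocityLeft",
                          value = abs(prog$ampLeft) / (prog$duration / 1000)),
    if (nProg) data.frame(descriptor = "averageVelocityRight",
                          value = abs(prog$ampRight) / (prog$duration / 1000))
  )
  list(saccades = sac, fixations = fix, units = units,
       scalars = c(nProgressive = nProg, nRegressive = nReg,
                   pctRegressive = pctReg),
       valid = TRUE)
}
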
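test_that("channel derivation and reconstruction are exact", {
  tr <- flatTrace()
  ch <- deriveChannels(tr)
  expect_equal(ch$vergence, rep(4, length(tr@time)))
  expect_equal(ch$conjugate, rep(0, length(tr@time)))
  # identical eyes: vergence vanishes, conjugate equals either eye
  eq <- new("BinocularTrace", time = tr@time, left = tr@left,
            right = tr@left, sampleRate = 200, events = tr@events)
  ch2 <- deriveChannels(eq)
  expect_equal(ch2$vergence, rep(0, length(tr@time)))
  expect_equal(ch2$conjugate, eq@left)
  # round-trip on an arbitrary binocular trace
  rec <- generateTestRecording(saccadeProtocol(2, 2), saccadeKinematics(),
                               seed = 3)
  ch3 <- deriveChannels(rec$trace)
  expect_equal(ch3$conjugate + ch3$vergence / 2, rec$trace@left,
               tolerance = 1e-12)
  expect_equal(ch3$conjugate - ch3$vergence / 2, rec$trace@right,
               tolerance = 1e-12)
})

test_that("velocity differentiation is exact on polynomial inputs", {
  cfg <- extractionConfig()
  expect_equal(traceVelocity(rep(3, 100), 200, cfg), rep(0, 100))
  ramp <- seq(0, 4.95, by = 0.05)  # 10 deg/s at 200 Hz
  v <- traceVelocity(ramp, 200, cfg)
  expect_equal(v[2:99], rep(10, 98), tolerance = 1e-9)
  # without smoothing as well
  v0 <- traceVelocity(ramp, 200, extractionConfig(smoothWindow = 1))
  expect_equal(v0[2:99], rep(10, 98), tolerance = 1e-9)
  expect_error(traceVelocity(c(1, 2), 200, cfg), "3 samples")
})

test_that("numerical peak velocity matches the analytic profile peak", {
  tr <- withr::with_seed(8, generateSaccadeTrial("saccadeRight", 1501,
                                                 cleanSaccade()))
  conj <- (tr$left + tr$right) / 2
  v <- traceVelocity(conj, 200)
  expect_lt(abs(max(abs(v)) - tr$truth$peakVelocity) / tr$truth$peakVelocity,
            0.02)
})

test_that("vergence detection returns none on flat input and finds the first movement", {
  tr <- flatTrace()
  ch <- deriveChannels(tr)
  expect_null(detectVergenceMovement(ch$vergence, tr@time, c(0.5, 2.5)))
  # two successive movements: the first one is returned
  rate <- 200
  tm <- seq_len(3 * rate) / rate
  pos <- 2 * raisedCosine((tm - 0.8) / 0.2) + 3 * raisedCosine((tm - 2.0) / 0.2)
  seg <- detectVergenceMovement(pos, tm, c(0.5, 3))
  expect_s4_class(seg, "MovementSegment")
  # brute-force oracle: first sample whose |velocity| exceeds 5 deg/s
  v <- traceVelocity(pos, rate)
  first <- which(tm >= 0.5 & abs(v) >= 5)[1]
  expect_lt(abs(seg@onset - tm[first]), 0.01)
  expect_lt(seg@offset, 1.5)
})

test_that("noiseless vergence onset is recovered within one sample", {
  rec <- generateTestRecording(vergenceProtocol(5, 5), cleanVergence(),
                               seed = 15)
  ch <- deriveChannels(rec$trace)
  for (i in seq_len(nrow(rec$truth))) {
    on <- rec$truth$targetOnset[i]
    seg <- detectVergenceMovement(ch$vergence, rec$trace@time, c(on, on + 2))
    expect_lt(abs(seg@onset - rec$truth$moveOnset[i]) * 1000, 5)
  }
})

test_that("saccade detection recovers amplitude and obeys the two-rule equivalence", {
  expect_null(detectSaccade((flatTrace()@left + flatTrace()@right) / 2,
                            flatTrace()@time, c(0.5, 2.5)))
  rec <- generateTestRecording(saccadeProtocol(3, 3), cleanSaccade(),
                               seed = 16)
  ch <- deriveChannels(rec$trace)
  v <- traceVelocity(ch$conjugate, 200)
  for (i in seq_len(nrow(rec$truth))) {
    on <- rec$truth$targetOnset[i]
    seg <- detectSaccade(ch$conjugate, rec$trace@time, c(on, on + 2))
    expect_lt(abs(abs(seg@amplitude) - 20), 0.15)
    # 10% of a ~400 deg/s peak is the 40 deg/s floor: bounds from the
    # fixed-floor rule alone match the refined bounds within one sample
    # (brute force over the first contiguous supra-floor run)
    idx <- which(rec$trace@time >= on & rec$trace@time <= on + 2 &
                   abs(v) >= 40)
    run <- idx[seq_len(which(c(diff(idx), 2) > 1)[1])]
    expect_lt(abs(seg@onset - rec$trace@time[run[1]]), 0.0051)
    expect_lt(abs(seg@offset - rec$trace@time[run[length(run)]]), 0.0051)
  }
})

test_that("trial descriptors satisfy their defining identities", {
  rec <- generateTestRecording(vergenceProtocol(5, 5), cleanVergence(),
                               seed = 17)
  tab <- extractTrials(rec$trace, test = "vergence")
  expect_true(all(tab$valid))
  # additivity exact by construction
  expect_equal(tab$totalAmplitude, tab$phasicAmplitude + tab$amp160,
               tolerance = 1e-12)
  expect_equal(tab$totalDuration, tab$phasicDuration + 160, tolerance = 1e-12)
  # average velocity identity
  expect_equal(tab$averageVelocity,
               abs(tab$totalAmplitude) / (tab$totalDuration / 1000),
               tolerance = 1e-12)
  # no drift configured: disconjugate drift at the noise floor
  expect_lt(max(abs(c(tab$drift1, tab$drift2))), 0.02)
})

test_that("additivity also holds exactly on noisy recordings", {
  rec <- generateTestRecording(saccadeProtocol(5, 5), saccadeKinematics(),
                               seed = 18)
  tab <- extractTrials(rec$trace, test = "saccade")
  ok <- tab$valid
  expect_gt(sum(ok), 0)
  expect_equal(tab$totalAmplitude[ok], tab$phasicAmplitude[ok] + tab$amp160[ok],
               tolerance = 1e-12)
})

test_that("descriptors recover noiseless ground truth", {
  recV <- generateTestRecording(vergenceProtocol(10, 10), cleanVergence(),
                                seed = 19)
  tabV <- extractTrials(recV$trace, test = "vergence")
  expect_lt(max(abs(tabV$latency - recV$truth$latency)), 5)
  expect_lt(max(abs(tabV$totalAmplitude - recV$truth$amplitude)), 0.1)
  expect_lt(max(abs(tabV$peakVelocity - recV$truth$peakVelocity) /
                  recV$truth$peakVelocity), 0.02)
  recS <- generateTestRecording(saccadeProtocol(10, 10), cleanSaccade(),
                                seed = 20)
  tabS <- extractTrials(recS$trace, test = "saccade")
  expect_lt(max(abs(tabS$latency - recS$truth$latency)), 5)
  expect_lt(max(abs(tabS$totalAmplitude - recS$truth$amplitude)), 0.1)
  expect_lt(max(abs(tabS$peakVelocity - recS$truth$peakVelocity) /
                  recS$truth$peakVelocity), 0.02)
})

test_that("configured drift is recovered in the disconjugate drift windows", {
  p <- vergenceKinematics(noiseSD = 0, blinkProb = 0, driftLeft = 0.4,
                          driftRight = 0.1, driftTau = 100)
  rec <- generateTestRecording(vergenceProtocol(5, 5), p, seed = 25)
  tab <- extractTrials(rec$trace, test = "vergence")
  # oracle: (dL - dR) * (1 - exp(-w / tau)) from the generator model
  expect1 <- 0.3 * (1 - exp(-80 / 100))
  expect2 <- 0.3 * (1 - exp(-160 / 100))
  expect_lt(max(abs(tab$drift1 - expect1)), 0.05)
  expect_lt(max(abs(tab$drift2 - expect2)), 0.05)
})

test_that("raising the vergence threshold never yields an earlier onset", {
  rec <- generateTestRecording(vergenceProtocol(3, 3), vergenceKinematics(),
                               seed = 26)
  ch <- deriveChannels(rec$trace)
  for (i in seq_len(nrow(rec$truth))) {
    on <- rec$truth$targetOnset[i]
    onsets <- vapply(c(3, 5, 8, 12, 20), function(thr) {
      seg <- detectVergenceMovement(ch$vergence, rec$trace@time, c(on, on + 2),
                                    extractionConfig(vergenceThreshold = thr))
      if (is.null(seg)) Inf else seg@onset
    }, numeric(1))
    expect_true(all(diff(onsets) >= -1e-12))
  }
})

test_that("blinks invalidate trials and propagate as aberrant rows", {
  p <- saccadeKinematics(blinkProb = 1, noiseSD = 0)
  rec <- generateTestRecording(saccadeProtocol(4, 4), p, seed = 27)
  tab <- extractTrials(rec$trace, test = "saccade")
  expect_true(all(!tab$valid))
  expect_true(all(is.na(tab$latency)))
})

test_that("reading descriptors count and classify saccades correctly", {
  p <- readingKinematics(noiseSD = 0, regressionProb = 0.2)
  r <- generateReadingTrace(60, p, seed = 28)
  d <- computeReadingDescriptors(r$trace)
  expect_true(d$valid)
  expect_identical(unname(d$scalars["nProgressive"]),
                   as.numeric(r$truth$nProgressive))
  expect_identical(unname(d$scalars["nRegressive"]),
                   as.numeric(r$truth$nRegressive))
  expect_equal(unname(d$scalars["pctRegressive"]),
               100 * r$truth$nRegressive / r$truth$nProgressive)
  # monotone staircase: no regressions at all
  p0 <- readingKinematics(noiseSD = 0, regressionProb = 0, wordsPerLine = 1e6)
  r0 <- generateReadingTrace(30, p0, seed = 29)
  d0 <- computeReadingDescriptors(r0$trace)
  expect_identical(unname(d0$scalars["nRegressive"]), 0)
  expect_true(all(d0$saccades$class == "progressive"))
})

test_that("fixation durations are recovered from the trace", {
  # near-deterministic fixations: gamma with very large shape
  p <- readingKinematics(fixationMean = 250, fixationShape = 1e6, noiseSD = 0)
  r <- generateReadingTrace(40, p, seed = 30)
  d <- computeReadingDescriptors(r$trace)
  expect_lt(abs(mean(d$fixations$duration) - 250), 10)
})

test_that("an empty reading trace is flagged invalid", {
  tr <- flatTrace()
  d <- computeReadingDescriptors(tr)
  expect_false(d$valid)
  expect_true(is.na(d$scalars["pctRegressive"]))
})
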
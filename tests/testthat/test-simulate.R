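test_that("seeded generation is deterministic", {
  a <- generateTestRecording(vergenceProtocol(2, 2), vergenceKinematics(),
                             seed = 11)
  b <- generateTestRecording(vergenceProtocol(2, 2), vergenceKinematics(),
                             seed = 11)
  expect_identical(a, b)
  r1 <- generateReadingTrace(30, seed = 4)
  r2 <- generateReadingTrace(30, seed = 4)
  expect_identical(r1, r2)
})

test_that("noiseless traces pass through their ground-truth waypoints", {
  tr <- withr::with_seed(2, generateVergenceTrial("convergence", 1500,
                                                  cleanVergence()))
  verg <- tr$left - tr$right
  expect_equal(verg[1], vergenceAngle(0.40), tolerance = 1e-10)
  expect_lt(abs(verg[length(verg)] - vergenceAngle(0.20)), 0.01)
  td <- withr::with_seed(3, generateVergenceTrial("divergence", 1500,
                                                  cleanVergence()))
  vd <- td$left - td$right
  expect_lt(abs(vd[length(vd)] - vergenceAngle(1.50)), 0.01)
})

test_that("saccade trials honour the configured disconjugacy", {
  # symmetric case: both eyes identical up to the fixation vergence offset
  tr <- withr::with_seed(5, generateSaccadeTrial("saccadeRight", 1500,
                                                 cleanSaccade()))
  v0 <- vergenceAngle(0.40)
  expect_equal(tr$left - v0 / 2, tr$right + v0 / 2, tolerance = 1e-10)
  # configured disconjugacy appears as the left-minus-right amplitude gap
  p <- cleanSaccade(); p@disconjugacy <- 0.5
  tr2 <- withr::with_seed(6, generateSaccadeTrial("saccadeLeft", 1500, p))
  n <- length(tr2$left)
  ampL <- tr2$left[n] - tr2$left[1]
  ampR <- tr2$right[n] - tr2$right[1]
  expect_lt(abs((ampL - ampR) - 0.5), 0.01)
})

test_that("blink artifacts are flagged and visible in the trace", {
  p <- saccadeKinematics(blinkProb = 1, noiseSD = 0)
  rec <- generateTestRecording(saccadeProtocol(3, 3), p, seed = 9)
  expect_true(all(rec$truth$blink))
  expect_true(any(abs(rec$trace@left) > 40 | abs(rec$trace@right) > 40))
})

test_that("drawn latencies recover the configured distribution", {
  p <- vergenceKinematics(latencyMean = 200, latencySD = 30, noiseSD = 0,
                          blinkProb = 0)
  rec <- generateTestRecording(vergenceProtocol(500, 500), p, seed = 13)
  lat <- rec$truth$latency
  se <- 30 / sqrt(length(lat))
  expect_lt(abs(mean(lat) - 200), 2 * se)
  expect_lt(abs(sd(lat) - 30), 3)
})

test_that("reading traces respect the regression probability", {
  # zero probability: no regressions at all
  p0 <- readingKinematics(regressionProb = 0, noiseSD = 0)
  r0 <- generateReadingTrace(40, p0, seed = 21)
  expect_identical(r0$truth$nRegressive, 0L)
  expect_gt(r0$truth$nProgressive, 0)
  # empirical regression fraction within the binomial 95% CI of p = 0.2
  p2 <- readingKinematics(regressionProb = 0.2)
  r2 <- generateReadingTrace(2000, p2, seed = 22)
  draws <- r2$truth$nProgressive + r2$truth$nRegressive
  phat <- r2$truth$nRegressive / draws
  expect_lt(abs(phat - 0.2), 1.96 * sqrt(0.2 * 0.8 / draws))
})

test_that("reading speed equals words over trace minutes", {
  r <- generateReadingTrace(150, seed = 23)
  expect_equal(r$speed, 150 / (r$truth$duration / 60))
  expect_equal(r$speed, r$truth$speed)
})

test_that("cohorts are deterministic and extensible by subject substream", {
  spec <- cohortSpec(nControl = 3, nDyslexic = 3, readingWords = 20,
                     vergenceProtocol = vergenceProtocol(2, 2),
                     saccadeProtocol = saccadeProtocol(2, 2), seed = 77)
  a <- generateCohort(spec)
  b <- generateCohort(spec)
  expect_identical(a@subjects, b@subjects)
  expect_identical(a@traits, b@traits)
})

test_that("noise-free speed model reproduces the linear prediction exactly", {
  spec <- cohortSpec(nControl = 5, nDyslexic = 5, readingWords = 15,
                     vergenceProtocol = vergenceProtocol(2, 2),
                     saccadeProtocol = saccadeProtocol(2, 2),
                     speedModel = list(intercept = 120,
                                       coefficients = c(vergenceLatency = -8,
                                                        saccadeLatency = -5),
                                       noiseSD = 0),
                     seed = 31)
  co <- generateCohort(spec)
  tr <- co@traits
  # independent recomputation of the configured linear model
  z <- function(x) (x - mean(x)) / sd(x)
  expected <- pmax(120 - 8 * z(tr$vergenceLatency) - 5 * z(tr$saccadeLatency),
                   10)
  expect_equal(tr$readingSpeed, expected, tolerance = 1e-12)
})

test_that("zero group offsets make the groups exchangeable", {
  co <- generateCohort(cohortSpec(nControl = 150, nDyslexic = 150,
                                  readingWords = 10,
                                  vergenceProtocol = vergenceProtocol(1, 1),
                                  saccadeProtocol = saccadeProtocol(1, 1),
                                  groupOffsets = list(latencyAddMs = 0,
                                                      velocityMul = 1,
                                                      driftMul = 1,
                                                      regressionMul = 1),
                                  seed = 41))
  tr <- co@traits
  dys <- tr$group == "dyslexic"
  # trait means differ by no more than 3 standard errors under the null
  for (col in c("vergenceLatency", "saccadeLatency", "velocityScale")) {
    se <- sd(tr[[col]]) * sqrt(2 / 150)
    expect_lt(abs(mean(tr[[col]][dys]) - mean(tr[[col]][!dys])), 3 * se)
  }
})
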
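# Shared fixtures, all built in code.

# Noise-free kinematics (no drift, no blinks) for recovery checks.
cleanVergence <- function(...) {
  vergenceKinematics(noiseSD = 0, blinkProb = 0, driftLeft = 0,
                     driftRight = 0, ...)
}

cleanSaccade <- function(...) {
  saccadeKinematics(noiseSD = 0, blinkProb = 0, driftLeft = 0,
                    driftRight = 0, disconjugacy = 0, ...)
}

# Gaussian feature matrix with balanced labels; optionally one feature
# separated between groups and a speed linearly tied to some features.
gaussianFeatures <- function(n = 40, p = 10, seed = 1, separation = 0,
                             speedBeta = NULL, speedNoise = 0) {
  withr::with_seed(seed, {
    values <- matrix(rnorm(p * n), nrow = p,
                     dimnames = list(sprintf("test.f%02d.mean", seq_len(p)),
                                     sprintf("S%03d", seq_len(n))))
    group <- rep(c("control", "dyslexic"), length.out = n)
    values[1, group == "dyslexic"] <-
      values[1, group == "dyslexic"] + separation
    speed <- rep(100, n)
    if (!is.null(speedBeta)) {
      speed <- 100 + as.numeric(t(values[seq_along(speedBeta), , drop = FALSE]) %*%
                                  speedBeta)
      if (speedNoise > 0) speed <- speed + rnorm(n, 0, speedNoise)
    }
    featureMatrix(values, group = group, readingSpeed = speed)
  })
}

# A single noiseless synthetic movement trace for detector tests.
flatTrace <- function(seconds = 3, rate = 200) {
  n <- seconds * rate
  new("BinocularTrace", time = seq_len(n) / rate - 1 / rate,
      left = rep(2, n), right = rep(-2, n), sampleRate = rate,
      events = data.frame(onset = 0.5, kind = "convergence"))
}
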
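# internal helpers: seeding and the raised-cosine movement profile

# Evaluate code with a temporarily seeded RNG, restoring the caller's state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream seed: master seed plus a counter, folded into the
# 32-bit positive range so cohorts are extensible without perturbing earlier
# subjects.
substreamSeed <- function(master, counter) {
  as.integer((as.numeric(master) %% 2147483647 + 10007 * as.numeric(counter)) %%
               2147483647)
}

# Raised-cosine position ramp: 0 at s = 0, 1 at s = 1, velocity
# (pi / 2) * sin(pi * s), peak velocity pi / 2 at midpoint.
raisedCosine <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  (1 - cos(pi * s)) / 2
}

# Movement duration (s) implied by the main-sequence slope under the
# raised-cosine profile: Vp = slope * |A| and Vp = pi * |A| / (2 * D).
profileDuration <- function(peakVelocityScale) pi / (2 * peakVelocityScale)

# Exponential drift shape, 0 at t = 0, 1 asymptotically; tau in seconds.
driftShape <- function(t, tau) ifelse(t <= 0, 0, 1 - exp(-t / tau))

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
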
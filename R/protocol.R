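#' Stimulus protocols
#'
#' Constructors for the two REMOBI-style test protocols. The vergence test
#' presents a fixation LED at 0.40 m (a ~9 degree vergence demand) for a
#' uniformly drawn 1400-2000 ms, followed for 2000 ms by a target at either
#' 0.20 m (convergence, to ~17 degrees) or 1.50 m (divergence, to ~2 degrees),
#' 20 trials of each kind pseudo-randomly interleaved, in an overlap paradigm
#' (fixation LED stays lit 200 ms into the target period). The saccade test
#' presents lateral targets at 20 degrees of eccentricity, 20 left and 20
#' right, with the same timing.
#'
#' @param nConvergence,nDivergence,nLeft,nRight trials per target kind.
#' @param fixationRange fixation-duration range (ms).
#' @param targetDuration target illumination (ms).
#' @param overlap overlap period (ms).
#' @param fixationDistance,convergenceDistance,divergenceDistance target
#'   distances (m).
#' @param eccentricity saccade-target eccentricity (deg).
#' @param interocular interocular distance (m).
#' @return a [StimulusProtocol] object.
#' @export
vergenceProtocol <- function(nConvergence = 20, nDivergence = 20,
                             fixationRange = c(1400, 2000),
                             targetDuration = 2000, overlap = 200,
                             fixationDistance = 0.40,
                             convergenceDistance = 0.20,
                             divergenceDistance = 1.50,
                             interocular = 0.060) {
  new("StimulusProtocol", kind = "vergence",
      counts = c(convergence = as.integer(nConvergence),
                 divergence = as.integer(nDivergence)),
      fixationRange = fixationRange, targetDuration = targetDuration,
      overlap = overlap, fixationDistance = fixationDistance,
      convergenceDistance = convergenceDistance,
      divergenceDistance = divergenceDistance,
      eccentricity = NA_real_, interocular = interocular)
}

#' @rdname vergenceProtocol
#' @export
saccadeProtocol <- function(nLeft = 20, nRight = 20,
                            fixationRange = c(1400, 2000),
                            targetDuration = 2000, overlap = 200,
                            fixationDistance = 0.40, eccentricity = 20,
                            interocular = 0.060) {
  new("StimulusProtocol", kind = "saccade",
      counts = c(saccadeLeft = as.integer(nLeft),
                 saccadeRight = as.integer(nRight)),
      fixationRange = fixationRange, targetDuration = targetDuration,
      overlap = overlap, fixationDistance = fixationDistance,
      convergenceDistance = NA_real_, divergenceDistance = NA_real_,
      eccentricity = eccentricity, interocular = interocular)
}

#' Draw the trial sequence of a protocol
#'
#' Interleaves the protocol's two target kinds pseudo-randomly and draws each
#' trial's fixation duration uniformly from the protocol range, using the
#' current RNG state.
#'
#' @param protocol a [StimulusProtocol].
#' @return data.frame with columns `kind` and `fixationMs`.
#' @export
drawTrials <- function(protocol) {
  kinds <- rep(names(protocol@counts), protocol@counts)
  kinds <- sample(kinds)
  data.frame(
    kind = kinds,
    fixationMs = runif(length(kinds), protocol@fixationRange[1],
                       protocol@fixationRange[2])
  )
}
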
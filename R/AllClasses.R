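#' @import methods
#' @importFrom stats approx cor cor.test cov dnorm lm.fit predict quantile
#'   rbinom rgamma rnorm runif sd setNames coef
#' @importFrom utils head read.delim write.table modifyList
NULL

#' Kinematic parameters of a simulated eye movement
#'
#' Describes the trial-to-trial kinematics used by the trace generator for one
#' movement type (vergence or saccade): the latency distribution, the
#' main-sequence velocity scaling, post-movement drift per eye, binocular
#' disconjugacy, measurement noise and the blink-artifact probability.
#'
#' @slot latencyMean mean latency from target onset to movement onset (ms).
#' @slot latencySD trial-to-trial latency standard deviation (ms).
#' @slot peakVelocityScale main-sequence slope in (deg/s) per deg of movement
#'   amplitude; together with the raised-cosine profile it fixes the movement
#'   duration as pi / (2 * scale) seconds.
#' @slot driftLeft,driftRight asymptotic post-movement drift amplitude of each
#'   eye (deg, rightward positive).
#' @slot driftTau exponential drift time constant (ms).
#' @slot disconjugacy left-minus-right amplitude difference of a saccade (deg).
#' @slot noiseSD white position-noise standard deviation per sample (deg).
#' @slot blinkProb probability that a trial contains a blink artifact.
#' @name KinematicParams-class
#' @aliases KinematicParams
#' @exportClass KinematicParams
setClass("KinematicParams",
  representation(
    latencyMean = "numeric", latencySD = "numeric",
    peakVelocityScale = "numeric",
    driftLeft = "numeric", driftRight = "numeric", driftTau = "numeric",
    disconjugacy = "numeric", noiseSD = "numeric", blinkProb = "numeric"
  )
)

setValidity("KinematicParams", function(object) {
  msg <- character()
  if (object@latencySD < 0) msg <- c(msg, "latencySD must be >= 0")
  if (object@latencyMean <= 0) msg <- c(msg, "latencyMean must be > 0")
  if (object@peakVelocityScale <= 0) msg <- c(msg, "peakVelocityScale must be > 0")
  if (object@driftTau <= 0) msg <- c(msg, "driftTau must be > 0")
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  if (object@blinkProb < 0 || object@blinkProb > 1)
    msg <- c(msg, "blinkProb must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Reading-trace parameters
#'
#' Kinematics of the simulated reading recording: gamma-distributed fixation
#' durations, progressive/regressive saccade amplitudes, the regression
#' probability, line geometry and per-fixation disconjugate drift.
#'
#' @slot fixationMean mean fixation duration (ms).
#' @slot fixationShape gamma shape parameter of the fixation-duration
#'   distribution (the scale is fixationMean / fixationShape).
#' @slot progressiveAmplitude rightward reading-saccade amplitude (deg).
#' @slot regressiveAmplitude leftward regression amplitude (deg, negative).
#' @slot regressionProb probability that a word is followed by a regression.
#' @slot wordsPerLine words per text line; line breaks trigger a large
#'   leftward return sweep which the extractor excludes from regressions.
#' @slot peakVelocityScale main-sequence slope, (deg/s)/deg.
#' @slot driftLeft,driftRight,driftTau post-saccadic drift per eye as in
#'   [KinematicParams].
#' @slot noiseSD position noise SD (deg).
#' @name ReadingParams-class
#' @aliases ReadingParams
#' @exportClass ReadingParams
setClass("ReadingParams",
  representation(
    fixationMean = "numeric", fixationShape = "numeric",
    progressiveAmplitude = "numeric", regressiveAmplitude = "numeric",
    regressionProb = "numeric", wordsPerLine = "numeric",
    peakVelocityScale = "numeric",
    driftLeft = "numeric", driftRight = "numeric", driftTau = "numeric",
    noiseSD = "numeric"
  )
)

setValidity("ReadingParams", function(object) {
  msg <- character()
  if (object@fixationMean <= 0) msg <- c(msg, "fixationMean must be > 0")
  if (object@fixationShape <= 0) msg <- c(msg, "fixationShape must be > 0")
  if (object@progressiveAmplitude <= 0)
    msg <- c(msg, "progressiveAmplitude must be > 0")
  if (object@regressiveAmplitude >= 0)
    msg <- c(msg, "regressiveAmplitude must be < 0")
  if (object@regressionProb < 0 || object@regressionProb > 1)
    msg <- c(msg, "regressionProb must lie in [0, 1]")
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Stimulus protocol for a REMOBI-style test
#'
#' Geometry and timing of one oculomotor test: target distances on the median
#' plane (vergence) or eccentricity (saccades), per-trial fixation-duration
#' range, target duration and the overlap period. The two target kinds of a
#' test are pseudo-randomly interleaved when trials are drawn.
#'
#' @slot kind "vergence" or "saccade".
#' @slot counts named integer vector of trials per target kind.
#' @slot fixationRange two-element range (ms) from which each trial's fixation
#'   duration is drawn uniformly.
#' @slot targetDuration target illumination time (ms).
#' @slot overlap overlap period during which fixation and target LEDs are both
#'   lit (ms).
#' @slot fixationDistance,convergenceDistance,divergenceDistance distances (m).
#' @slot eccentricity horizontal saccade-target eccentricity (deg).
#' @slot interocular interocular distance used for vergence geometry (m).
#' @name StimulusProtocol-class
#' @aliases StimulusProtocol
#' @exportClass StimulusProtocol
setClass("StimulusProtocol",
  representation(
    kind = "character", counts = "integer",
    fixationRange = "numeric", targetDuration = "numeric", overlap = "numeric",
    fixationDistance = "numeric", convergenceDistance = "numeric",
    divergenceDistance = "numeric", eccentricity = "numeric",
    interocular = "numeric"
  )
)

setValidity("StimulusProtocol", function(object) {
  msg <- character()
  if (!object@kind %in% c("vergence", "saccade"))
    msg <- c(msg, "kind must be 'vergence' or 'saccade'")
  if (length(object@counts) != 2 || any(object@counts < 0))
    msg <- c(msg, "counts must name exactly two non-negative target kinds")
  if (length(object@fixationRange) != 2 ||
      object@fixationRange[1] > object@fixationRange[2] ||
      object@fixationRange[1] <= 0)
    msg <- c(msg, "fixationRange must be an increasing positive pair (ms)")
  if (object@targetDuration <= 0) msg <- c(msg, "targetDuration must be > 0")
  if (length(msg)) msg else TRUE
})

#' Binocular eye-position trace
#'
#' A uniformly sampled binocular horizontal eye-position recording (left and
#' right eye, degrees, rightward positive) with stimulus-event annotations.
#'
#' @slot time sample times (s), strictly increasing.
#' @slot left,right eye positions (deg).
#' @slot sampleRate sampling rate (Hz).
#' @slot events data.frame with columns `onset` (s) and `kind` (character),
#'   one row per stimulus event (target onsets).
#' @name BinocularTrace-class
#' @aliases BinocularTrace
#' @exportClass BinocularTrace
setClass("BinocularTrace",
  representation(
    time = "numeric", left = "numeric", right = "numeric",
    sampleRate = "numeric", events = "data.frame"
  )
)

setValidity("BinocularTrace", function(object) {
  msg <- character()
  n <- length(object@time)
  if (length(object@left) != n || length(object@right) != n)
    msg <- c(msg, "time, left and right must have equal length")
  if (n > 1 && any(diff(object@time) <= 0))
    msg <- c(msg, "time must be strictly increasing")
  if (object@sampleRate <= 0) msg <- c(msg, "sampleRate must be > 0")
  if (!all(c("onset", "kind") %in% names(object@events)))
    msg <- c(msg, "events must have columns 'onset' and 'kind'")
  if (length(msg)) msg else TRUE
})

#' Detected movement segment
#'
#' One velocity-threshold-bounded movement on a derived channel: the initial
#' phasic component of a vergence movement or a saccade.
#'
#' @slot channel channel the detection ran on ("vergence" or "conjugate").
#' @slot onset,offset interpolated threshold-crossing times (s).
#' @slot amplitude position change between onset and offset (deg, signed).
#' @slot peakVelocity maximum absolute velocity inside the segment (deg/s).
#' @name MovementSegment-class
#' @aliases MovementSegment
#' @exportClass MovementSegment
setClass("MovementSegment",
  representation(
    channel = "character", onset = "numeric", offset = "numeric",
    amplitude = "numeric", peakVelocity = "numeric"
  )
)

setValidity("MovementSegment", function(object) {
  if (object@offset <= object@onset) "offset must exceed onset" else TRUE
})

#' Cohort specification for the synthetic study
#'
#' Fully determines a synthetic cohort: group sizes, control-group kinematic
#' parameters per test, additive/multiplicative dyslexic-group offsets,
#' between-subject trait variability, the linear reading-speed model on the
#' subjects' true descriptor traits, the stimulus protocols and the master
#' seed. See [cohortSpec()] for defaults.
#'
#' @name CohortSpec-class
#' @aliases CohortSpec
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(
    nControl = "integer", nDyslexic = "integer",
    vergenceParams = "KinematicParams", saccadeParams = "KinematicParams",
    readingParams = "ReadingParams",
    groupOffsets = "list", subjectSD = "list", speedModel = "list",
    vergenceProtocol = "StimulusProtocol", saccadeProtocol = "StimulusProtocol",
    readingWords = "integer", seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nControl < 1L || object@nDyslexic < 1L)
    msg <- c(msg, "at least one subject per group is required")
  sm <- object@speedModel
  if (!all(c("intercept", "coefficients") %in% names(sm)))
    msg <- c(msg, "speedModel must contain intercept and coefficients")
  if (!is.null(sm$noiseSD) && sm$noiseSD < 0)
    msg <- c(msg, "speedModel noiseSD must be >= 0")
  if (object@readingWords < 1L) msg <- c(msg, "readingWords must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort
#'
#' Container returned by [generateCohort()]: one element per subject (traces
#' per test, per-trial ground truth, group label, reading speed), the
#' subject-level trait table and the generating [CohortSpec].
#'
#' @slot subjects list with one entry per subject.
#' @slot traits data.frame of true subject-level traits (one row per subject).
#' @slot spec the generating specification.
#' @name OculoCohort-class
#' @aliases OculoCohort
#' @exportClass OculoCohort
setClass("OculoCohort",
  representation(subjects = "list", traits = "data.frame", spec = "CohortSpec",
                 planted = "list")
)

#' Subjects-by-features table
#'
#' SummarizedExperiment-backed container for the per-subject descriptor
#' statistics: assay `values` holds the numeric features (rows) by subjects
#' (columns), assay `aberrant` the logical mask of aberrant cells. `rowData`
#' records test, dataset, descriptor and statistic per feature; `colData`
#' carries the group label and reading speed.
#'
#' @name FeatureMatrix-class
#' @aliases FeatureMatrix
#' @exportClass FeatureMatrix
setClass("FeatureMatrix", contains = "SummarizedExperiment")

#' Cross-validated classifier evaluation
#'
#' Per-fold and mean accuracy/sensitivity/specificity of one classifier under
#' stratified k-fold cross-validation with train-fitted standardization.
#'
#' @slot model roster identifier of the evaluated model.
#' @slot foldAssignments fold index per subject.
#' @slot confusions per-fold confusion counts (tp, fn, tn, fp).
#' @slot perFold folds x 3 matrix of accuracy/sensitivity/specificity (%).
#' @slot means named mean metrics over folds (%).
#' @slot predictions out-of-fold predicted labels, one per subject.
#' @slot standardizers per-fold train means and SDs.
#' @slot seed run seed.
#' @name CVEvaluation-class
#' @aliases CVEvaluation
#' @exportClass CVEvaluation
setClass("CVEvaluation",
  representation(
    model = "character", foldAssignments = "integer", confusions = "list",
    perFold = "matrix", means = "numeric", predictions = "factor",
    standardizers = "list", seed = "integer"
  )
)

#' Label-permutation significance result
#'
#' Observed mean cross-validated accuracy, the distribution of the same score
#' under label permutation, and the exceedance p-value.
#'
#' @slot model model identifier.
#' @slot observed observed mean CV accuracy (%).
#' @slot permuted permuted-label mean accuracies (%), length R.
#' @slot pValue exceedance probability (# permuted >= observed) / R.
#' @slot seed run seed.
#' @name PermutationResult-class
#' @aliases PermutationResult
#' @exportClass PermutationResult
setClass("PermutationResult",
  representation(
    model = "character", observed = "numeric", permuted = "numeric",
    pValue = "numeric", seed = "integer"
  )
)

setValidity("PermutationResult", function(object) {
  if (object@pValue < 0 || object@pValue > 1) "pValue must lie in [0, 1]" else TRUE
})

#' Cross-validated regression evaluation
#'
#' Pooled out-of-fold reading-speed predictions of one regression model with
#' fold-internal feature selection, plus the selection record.
#'
#' @slot model model identifier.
#' @slot predictions pooled out-of-fold predictions (words/min).
#' @slot truth observed reading speeds (words/min).
#' @slot mape mean absolute percentage error (%) of the pooled predictions.
#' @slot pearson Pearson correlation between pooled predictions and truth.
#' @slot foldAssignments fold index per subject.
#' @slot selection per-fold data.frames of selected features and their
#'   train-set correlations.
#' @slot seed run seed.
#' @name RegressionEvaluation-class
#' @aliases RegressionEvaluation
#' @exportClass RegressionEvaluation
setClass("RegressionEvaluation",
  representation(
    model = "character", predictions = "numeric", truth = "numeric",
    mape = "numeric", pearson = "numeric", foldAssignments = "integer",
    selection = "list", seed = "integer"
  )
)
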
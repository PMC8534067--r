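setMethod("show", "BinocularTrace", function(object) {
  cat(sprintf(
    "BinocularTrace: %d samples at %g Hz (%.1f s), %d events\n",
    length(object@time), object@sampleRate,
    if (length(object@time)) diff(range(object@time)) else 0,
    nrow(object@events)))
})

setMethod("show", "StimulusProtocol", function(object) {
  cat(sprintf("StimulusProtocol (%s): %s trials, fixation %g-%g ms, target %g ms, overlap %g ms\n",
              object@kind,
              paste(sprintf("%d %s", object@counts, names(object@counts)),
                    collapse = " + "),
              object@fixationRange[1], object@fixationRange[2],
              object@targetDuration, object@overlap))
})

setMethod("show", "MovementSegment", function(object) {
  cat(sprintf(
    "MovementSegment [%s]: %.3f-%.3f s, amplitude %.2f deg, peak %.1f deg/s\n",
    object@channel, object@onset, object@offset, object@amplitude,
    object@peakVelocity))
})

setMethod("show", "OculoCohort", function(object) {
  tb <- table(object@traits$group)
  cat(sprintf("OculoCohort: %d subjects (%s), seed %d\n",
              length(object@subjects),
              paste(sprintf("%d %s", tb, names(tb)), collapse = ", "),
              object@spec@seed))
})

setMethod("show", "CVEvaluation", function(object) {
  m <- object@means
  cat(sprintf(
    "CVEvaluation [%s]: accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%% (%d folds)\n",
    object@model, m["accuracy"], m["sensitivity"], m["specificity"],
    nrow(object@perFold)))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    "PermutationResult [%s]: observed %.2f%%, R = %d, p = %.3f\n",
    object@model, object@observed, length(object@permuted), object@pValue))
})

setMethod("show", "RegressionEvaluation", function(object) {
  cat(sprintf(
    "RegressionEvaluation [%s]: MAPE %.2f%%, Pearson r %.3f (n = %d)\n",
    object@model, object@mape, object@pearson, length(object@truth)))
})
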
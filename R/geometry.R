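#' Vergence angle demanded by a target distance
#'
#' Angle between the two lines of sight when both eyes fixate a point on the
#' median plane at the given distance: `2 * atan((ipd / 2) / distance)`,
#' in degrees. With the default 6.0 cm interocular distance the three
#' REMOBI target distances (0.40, 0.20, 1.50 m) give 8.58, 17.06 and 2.29
#' degrees, i.e. the nominal 9, 17 and 2 degree vergence demands after
#' rounding, and a convergence step of about 8 degrees.
#'
#' @param distance target distance (m); may be `Inf` (optical infinity).
#' @param interocular interocular distance (m), default 0.060.
#' @return vergence angle in degrees (vectorized over `distance`).
#' @examples
#' vergenceAngle(0.40)            # ~8.58 deg
#' vergenceAngle(0.20) - vergenceAngle(0.40)  # convergence step, ~8.5 deg
#' @export
vergenceAngle <- function(distance, interocular = 0.060) {
  stopIfNot(all(distance > 0), "distance must be > 0")
  stopIfNot(length(interocular) == 1 && interocular > 0,
            "interocular must be a single value > 0")
  2 * atan((interocular / 2) / distance) * 180 / pi
}
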
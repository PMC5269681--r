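#' Wrap angles to the principal branch (-180, 180]
#'
#' @param x Angles in degrees.
#' @return Angles wrapped into (-180, 180].
#' @examples
#' wrapAngle(c(185, -190, 180, 540))
#' @export
wrapAngle <- function(x) {
  stopifnot(is.numeric(x))
  x - 360 * ceiling((x - 180) / 360)
}

#' Unwrap an angle to the branch nearest a reference
#'
#' Returns `angle + k*360` for the integer k that minimizes the distance to
#' `reference`, so that |result - reference| <= 180. Umbrella series are
#' unwrapped to the branch of their window center before any statistics,
#' because window centers may span more than half a period (e.g. -320 to 38
#' degrees).
#'
#' @param angle Angles in degrees (vectorized).
#' @param reference Branch reference in degrees (scalar or vector).
#' @return Unwrapped angles in degrees.
#' @examples
#' unwrapToBranch(50, -310)   # -310
#' unwrapToBranch(170, -180)  # -190
#' @export
unwrapToBranch <- function(angle, reference) {
  stopifnot(is.numeric(angle), is.numeric(reference))
  angle + 360 * round((reference - angle) / 360)
}

#' Signed angular displacement in a chosen rotation sense
#'
#' The arc traversed from `start` to `end` going in the positive
#' (counter-increasing dihedral, here: major-groove) or negative
#' (minor-groove) direction, on a 360-degree period. The positive result lies
#' in [0, 360), the negative in (-360, 0]; their difference is 360 whenever
#' start and end are not congruent.
#'
#' For the flipping coordinate this is the bookkeeping that turns the
#' intra-helical minimum (e.g. 29 or 69 degrees) and the extra-helical state
#' (-135, congruent to 225) into required flipping arcs of 196 and 156
#' degrees (positive direction) or -204 (negative, from 69).
#'
#' @param start,end Angles in degrees.
#' @param direction "positive" or "negative".
#' @return Signed displacement in degrees.
#' @examples
#' angularPath(29, -135, "positive")   # 196
#' angularPath(69, -135, "positive")   # 156
#' angularPath(69, -135, "negative")   # -204
#' @export
angularPath <- function(start, end, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(start), is.numeric(end))
  d <- (end - start) %% 360
  if (direction == "positive") d else ifelse(d == 0, 0, d - 360)
}
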
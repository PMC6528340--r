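#' Wrap angles into [0, 2*pi)
#'
#' All torsional quantities in the package live on the circle; this is the
#' canonical representative used for storage and comparison.
#'
#' @param theta numeric vector of angles in radians.
#' @return numeric vector in `[0, 2*pi)`.
#' @export
wrapAngle <- function(theta) {
  out <- theta %% (2 * pi)
  # guard against 2*pi itself from floating-point roundoff
  out[out >= 2 * pi] <- 0
  out
}

#' Signed wrap into (-pi, pi]
#' @param theta numeric vector of angles in radians.
#' @return numeric vector in `(-pi, pi]`.
#' @export
wrapToPi <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

#' Circular distance on the 2*pi circle
#'
#' @param x,y numeric vectors of angles in radians (recycled).
#' @return elementwise `min(|x - y| mod 2pi, 2pi - |x - y| mod 2pi)`.
#' @export
circularDistance <- function(x, y) {
  d <- abs(x - y) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

degToRad <- function(x) x * pi / 180
radToDeg <- function(x) x * 180 / pi
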
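#' @include AllClasses.R
NULL

checkPositive <- function(...) {
  vals <- list(...)
  for (nm in names(vals))
    if (any(!is.finite(vals[[nm]])) || any(vals[[nm]] <= 0))
      stop("kernel hyperparameter '", nm, "' must be strictly positive",
           call. = FALSE)
  invisible(TRUE)
}

#' Squared-exponential kernel on the torsion circle
#'
#' `sigma2 * exp(-r^2 / (2 l^2))` summed in quadrature over dimensions,
#' where `r` is a per-dimension distance respecting the wraparound topology
#' of torsion angles. The default `"chordal"` distance `2 sin(|x - y| / 2)`
#' embeds the circle in the plane and keeps the kernel positive
#' semidefinite; `"wrapped"` is the geodesic distance
#' `min(|x - y|, 2*pi - |x - y|)` (closer to intuition but indefinite on
#' dense designs with long length scales); `"raw"` is the textbook kernel
#' on plain differences, ignoring the topology.
#'
#' @param x,y numeric vectors (points of equal dimension; scalars for 1-D).
#' @param l length scale(s), radians; scalar or per-dimension.
#' @param sigma2 variance.
#' @param distance one of `"chordal"`, `"wrapped"`, `"raw"`.
#' @return covariance value.
#' @export
kSE <- function(x, y, l, sigma2 = 1,
                distance = c("chordal", "wrapped", "raw")) {
  distance <- match.arg(distance)
  checkPositive(l = l, sigma2 = sigma2)
  if (length(x) != length(y)) stop("x and y must have equal length")
  r <- switch(distance,
              chordal = 2 * sin(circularDistance(x, y) / 2),
              wrapped = circularDistance(x, y),
              raw = abs(x - y))
  sigma2 * exp(-sum(r^2 / (2 * l^2)))
}

#' Periodic kernel
#'
#' `sigma2 * exp(-2 sin^2(pi |x - y| / p) / l^2)` per dimension, exactly
#' `p`-periodic in the difference `x - y`.
#'
#' @param x,y numeric vectors (points of equal dimension).
#' @param l length scale(s).
#' @param p period(s), radians; for a bond of integer periodicity `m` use
#'   `p = 2*pi/m`.
#' @param sigma2 variance.
#' @return covariance value.
#' @export
kPer <- function(x, y, l, p, sigma2 = 1) {
  checkPositive(l = l, p = p, sigma2 = sigma2)
  if (length(x) != length(y)) stop("x and y must have equal length")
  s <- sin(pi * abs(x - y) / p)
  sigma2 * exp(-sum(2 * s^2 / l^2))
}

#' Locally periodic product kernel
#'
#' The surrogate's covariance: over each torsion dimension, the product of a
#' unit-variance periodic factor (period fixed from the bond's chemistry)
#' and a unit-variance squared-exponential factor on the circular distance,
#' all scaled by a shared variance. The periodic factor encodes where the
#' torsional potential repeats; the SE factor lets amplitudes vary between
#' repeats.
#'
#' @param x,y numeric vectors of equal length `d`.
#' @param params list with `lPer`, `lSe` (length 1 or `d`), `periods`
#'   (radians, length `d`), `sigma2`, and optionally `circularSE` (default
#'   `TRUE`: chordal circle distance in the SE factor; `FALSE`: raw
#'   differences).
#' @return covariance value.
#' @export
kLocallyPeriodic <- function(x, y, params) {
  d <- length(x)
  if (length(y) != d) stop("x and y must have equal length")
  if (length(params$periods) != d)
    stop("params$periods must have one period per dimension")
  lPer <- rep(params$lPer, length.out = d)
  lSe <- rep(params$lSe, length.out = d)
  checkPositive(lPer = lPer, lSe = lSe, sigma2 = params$sigma2,
                periods = params$periods)
  circ <- !isFALSE(params$circularSE)
  s <- sin(pi * (x - y) / params$periods)
  r <- if (circ) 2 * sin(circularDistance(x, y) / 2) else abs(x - y)
  params$sigma2 * exp(-sum(2 * s^2 / lPer^2) - sum(r^2 / (2 * lSe^2)))
}

# per-dimension distance matrices between row sets X and Y, computed once
# and reused across hyperparameter evaluations during fitting
lpKernelPrecompute <- function(X, Y, periods, circularSE = TRUE) {
  d <- ncol(X)
  S2 <- vector("list", d)
  R2 <- vector("list", d)
  for (i in seq_len(d)) {
    D <- outer(X[, i], Y[, i], `-`)
    S2[[i]] <- sin(pi * D / periods[i])^2
    r <- if (circularSE) {
      a <- abs(D) %% (2 * pi)
      2 * sin(pmin(a, 2 * pi - a) / 2)  # chordal circle distance (PSD)
    } else abs(D)
    R2[[i]] <- r * r
  }
  list(S2 = S2, R2 = R2, d = d)
}

lpKernelFromPre <- function(pre, lPer, lSe, sigma2) {
  logK <- 0
  for (i in seq_len(pre$d))
    logK <- logK - (2 / lPer[i]^2) * pre$S2[[i]] -
      (0.5 / lSe[i]^2) * pre$R2[[i]]
  sigma2 * exp(logK)
}

# Gram matrix of the locally periodic kernel between row sets X and Y
# (noise-free). Vectorized over dimensions; the workhorse of gp fitting.
lpKernelMatrix <- function(X, Y, lPer, lSe, sigma2, periods,
                           circularSE = TRUE) {
  lpKernelFromPre(lpKernelPrecompute(X, Y, periods, circularSE),
                  rep(lPer, length.out = ncol(X)),
                  rep(lSe, length.out = ncol(X)), sigma2)
}
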
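#' @include gp.R
NULL

#' Acquisition specification
#'
#' @param kind one of `"EI"` (expected improvement), `"PI"` (probability of
#'   improvement), `"LCB"` (Gaussian-process lower confidence bound).
#' @param kappa exploration weight for LCB (`mu - kappa * sigma`); ignored
#'   otherwise. The default of 2 is a common choice; the weight trades off
#'   exploring high-variance regions against exploiting low predicted means.
#' @param candidates number of uniform random candidates scored in batch by
#'   the inner optimizer.
#' @param restarts number of top candidates refined by local search.
#' @return a validated list of class `"acquisitionSpec"`.
#' @export
acquisitionSpec <- function(kind = c("EI", "PI", "LCB"), kappa = 2,
                            candidates = 1000, restarts = 5) {
  kind <- match.arg(kind)
  stopifnot(kappa >= 0, restarts >= 1, candidates >= 1)
  structure(list(kind = kind, kappa = kappa,
                 candidates = as.integer(candidates),
                 restarts = as.integer(restarts)),
            class = "acquisitionSpec")
}

#' Acquisition function values
#'
#' With `z = (fBest - mu) / sigma`: PI is `Phi(z)`, EI is
#' `sigma * (z * Phi(z) + phi(z))`, and LCB is `mu - kappa * sigma`. For
#' minimization, higher is better for PI/EI and lower is better for LCB. At
#' `sigma = 0` the continuous limits apply: PI is 1 where `mu < fBest` and 0
#' elsewhere, EI is 0, LCB equals `mu`.
#'
#' @param spec an [acquisitionSpec()] (or a kind string).
#' @param mu,sigma posterior mean and standard deviation (vectors).
#' @param fBest best (lowest) objective value observed so far.
#' @param kappa overrides the spec's kappa when given.
#' @return numeric vector of acquisition values.
#' @export
acqValue <- function(spec, mu, sigma, fBest, kappa = NULL) {
  if (is.character(spec)) spec <- acquisitionSpec(spec,
                                                  kappa = if (is.null(kappa)) 2 else kappa)
  if (is.null(kappa)) kappa <- spec$kappa
  if (any(sigma < 0)) stop("sigma must be non-negative")
  switch(spec$kind,
    PI = {
      out <- ifelse(sigma > 0, stats::pnorm((fBest - mu) / sigma),
                    as.numeric(mu < fBest))
      out
    },
    EI = {
      z <- ifelse(sigma > 0, (fBest - mu) / sigma, 0)
      ifelse(sigma > 0, sigma * (z * stats::pnorm(z) + stats::dnorm(z)), 0)
    },
    LCB = mu - kappa * sigma
  )
}

# internal orientation: a score where larger is always better
acqScore <- function(spec, mu, sigma, fBest) {
  v <- acqValue(spec, mu, sigma, fBest)
  if (spec$kind == "LCB") -v else v
}

#' Propose the next torsion vector
#'
#' Inner optimization of the acquisition over the torsion hypercube:
#' `spec$candidates` uniform random points are scored in one batch, the top
#' `spec$restarts` are refined by derivative-free local search with
#' wraparound, and the best refined point wins (ties broken toward the
#' lowest-index candidate). Consumes the R random number stream, so the
#' proposal is deterministic given the RNG state.
#'
#' @param model a fitted [GPTorsionModel-class].
#' @param spec an [acquisitionSpec()].
#' @return numeric torsion vector in `[0, 2*pi)`.
#' @export
proposeNext <- function(model, spec = acquisitionSpec()) {
  d <- ncol(model@X)
  fBest <- min(model@y)
  pointPredict <- gpPredictor(model)
  scoreAt <- function(th) {
    pr <- pointPredict(wrapAngle(th))
    acqScore(spec, pr[[1]], sqrt(pr[[2]]), fBest)
  }
  cand <- matrix(stats::runif(spec$candidates * d, 0, 2 * pi),
                 ncol = d)
  pr <- predict(model, cand)
  scores <- acqScore(spec, pr$mean, sqrt(pr$var), fBest)
  top <- order(-scores)[seq_len(min(spec$restarts, nrow(cand)))]
  bestTheta <- cand[top[1], ]
  bestScore <- scores[top[1]]
  for (idx in top) {
    th0 <- cand[idx, ]
    ref <- tryCatch({
      if (d == 1) {
        o <- stats::optimize(function(t) -scoreAt(t),
                             lower = th0 - 0.5, upper = th0 + 0.5)
        list(par = o$minimum, value = o$objective)
      } else {
        o <- stats::optim(th0, function(t) -scoreAt(t),
                          method = "Nelder-Mead",
                          control = list(maxit = 120, reltol = 1e-9))
        list(par = o$par, value = o$value)
      }
    }, error = function(e) NULL)
    if (!is.null(ref) && is.finite(ref$value) && -ref$value > bestScore + 1e-15) {
      bestScore <- -ref$value
      bestTheta <- ref$par
    }
  }
  wrapAngle(bestTheta)
}
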
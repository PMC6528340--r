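#' @include kernels.R
NULL

#' Hyperparameter bounds for GP fitting
#'
#' Box constraints for the marginal-likelihood optimization, in normalized
#' output units and radians. Periods are never fitted; they are fixed from
#' the bonds' periodicities.
#'
#' @param lengthScale length-2 numeric, bounds for both length scales.
#' @param sigma2 length-2 numeric, bounds for the kernel variance.
#' @param noise length-2 numeric, bounds for the noise variance.
#' @return list of bounds.
#' @export
gpBounds <- function(lengthScale = c(0.05, 10), sigma2 = c(1e-3, 1e3),
                     noise = c(1e-6, 1e-1)) {
  stopifnot(lengthScale[1] > 0, sigma2[1] > 0, noise[1] > 0,
            diff(lengthScale) > 0, diff(sigma2) > 0, diff(noise) > 0)
  list(lengthScale = lengthScale, sigma2 = sigma2, noise = noise)
}

# jitter ladder used when the Cholesky factorization fails
.jitterLadder <- c(0, 1e-8, 1e-6, 1e-4)

cholWithJitter <- function(K, noise) {
  # jitter is scaled by the kernel's diagonal so the ladder keeps its
  # meaning whatever the fitted variance
  scale <- mean(diag(K))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  for (jit in .jitterLadder) {
    L <- tryCatch(chol(K + diag(noise + jit * scale, nrow(K))),
                  error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = jit * scale))
  }
  stop(errorCondition(
    "kernel matrix is not positive definite even with the maximal jitter",
    class = c("torsbo_conditioning_error", "error")))
}

# negative log marginal likelihood and its gradient in log-parameter space;
# theta = c(log lPer_1..d, log lSe_1..d, log sigma2, log noise); `pre` holds
# the precomputed per-dimension distance matrices for the training set
nlmlAndGrad <- function(theta, pre, yn, grad = TRUE) {
  n <- length(yn); d <- pre$d
  lPer <- exp(theta[seq_len(d)])
  lSe <- exp(theta[d + seq_len(d)])
  sigma2 <- exp(theta[2 * d + 1])
  noise <- exp(theta[2 * d + 2])
  Kf <- lpKernelFromPre(pre, lPer, lSe, sigma2)
  fac <- tryCatch(cholWithJitter(Kf, noise), error = function(e) NULL)
  if (is.null(fac)) return(list(value = 1e10, grad = rep(0, length(theta))))
  L <- fac$L
  alpha <- backsolve(L, forwardsolve(t(L), yn))
  nll <- 0.5 * sum(yn * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  if (!grad) return(list(value = nll, grad = NULL))
  # W = K^{-1} - alpha alpha^T; d(nll)/d(theta_j) = 0.5 tr(W dK/dtheta_j)
  Kinv <- chol2inv(L)
  W <- Kinv - tcrossprod(alpha)
  WK <- W * Kf
  g <- numeric(length(theta))
  for (i in seq_len(d)) {
    g[i] <- 0.5 * sum(WK * pre$S2[[i]]) * 4 / lPer[i]^2
    g[d + i] <- 0.5 * sum(WK * pre$R2[[i]]) / lSe[i]^2
  }
  g[2 * d + 1] <- 0.5 * sum(WK)
  g[2 * d + 2] <- 0.5 * sum(diag(W)) * noise
  list(value = nll, grad = g)
}

#' Log marginal likelihood of a hyperparameter setting
#'
#' Computed on internally normalized outputs (zero mean, unit scale), as
#' during fitting; useful for comparing hyperparameter candidates.
#'
#' @param X n x d matrix of torsion vectors.
#' @param y raw outputs.
#' @param periodicities integer periodicities per dimension.
#' @param params list with `lPer`, `lSe`, `sigma2`, `noise`.
#' @param circularSE logical.
#' @return log marginal likelihood (scalar).
#' @export
gpLogMarginalLikelihood <- function(X, y, periodicities, params,
                                    circularSE = TRUE) {
  X <- as.matrix(X)
  d <- ncol(X)
  yn <- normalizeY(y)$yn
  periods <- 2 * pi / periodicities
  theta <- log(c(rep(params$lPer, length.out = d),
                 rep(params$lSe, length.out = d),
                 params$sigma2, params$noise))
  pre <- lpKernelPrecompute(X, X, periods, circularSE)
  -nlmlAndGrad(theta, pre, yn, grad = FALSE)$value
}

normalizeY <- function(y) {
  m <- mean(y)
  s <- if (length(y) > 1) stats::sd(y) else 0
  if (!is.finite(s) || s <= 0) s <- 1
  list(yn = (y - m) / s, mean = m, sd = s)
}

#' Fit the Gaussian-process surrogate
#'
#' Normalizes the outputs to zero mean and unit scale, then maximizes the
#' log marginal likelihood over the length scales, kernel variance and noise
#' variance within box bounds, by multi-start L-BFGS-B with analytic
#' gradients in log-parameter space. Kernel periods stay fixed at
#' `2*pi / periodicity`: they encode the chemistry prior and are not fitted.
#' Cholesky failures escalate diagonal jitter from 1e-8 to 1e-4; only if the
#' largest jitter still fails does fitting signal a
#' `torsbo_conditioning_error`.
#'
#' @param X n x d matrix (rows are torsion vectors, radians).
#' @param y numeric outputs (raw energies), length n >= 1.
#' @param periodicities integer periodicity per dimension.
#' @param bounds from [gpBounds()].
#' @param nStarts number of optimizer starts (first start is warm/default).
#' @param warmStart optional `params` list from a previous fit, used as the
#'   first start.
#' @param circularSE use circular distance in the SE factor (default).
#' @param maxit L-BFGS-B iteration cap per start.
#' @return a fitted [GPTorsionModel-class].
#' @export
fitGP <- function(X, y, periodicities, bounds = gpBounds(), nStarts = 2,
                  warmStart = NULL, circularSE = TRUE, maxit = 50) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  stopifnot(n >= 1, length(y) == n, length(periodicities) == d)
  if (any(!is.finite(y))) stop("outputs must be finite")
  nz <- normalizeY(y)
  periods <- 2 * pi / periodicities
  lower <- log(c(rep(bounds$lengthScale[1], 2 * d), bounds$sigma2[1],
                 bounds$noise[1]))
  upper <- log(c(rep(bounds$lengthScale[2], 2 * d), bounds$sigma2[2],
                 bounds$noise[2]))
  starts <- list()
  if (!is.null(warmStart)) {
    starts[[1]] <- pmin(pmax(log(c(rep(warmStart$lPer, length.out = d),
                                   rep(warmStart$lSe, length.out = d),
                                   warmStart$sigma2, warmStart$noise)),
                             lower), upper)
  } else {
    starts[[1]] <- pmin(pmax(log(c(rep(1, d), rep(2, d), 1, 1e-4)),
                             lower), upper)
  }
  while (length(starts) < nStarts)
    starts[[length(starts) + 1]] <- lower + stats::runif(length(lower)) *
      (upper - lower)
  best <- NULL
  theta0 <- starts[[1]]
  if (maxit == 0) starts <- list()  # keep the warm start as-is
  pre <- lpKernelPrecompute(X, X, periods, circularSE)
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st,
                   fn = function(th) nlmlAndGrad(th, pre, nz$yn,
                                                 grad = FALSE)$value,
                   gr = function(th) nlmlAndGrad(th, pre, nz$yn)$grad,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  theta <- if (is.null(best)) theta0 else best$par
  lPer <- exp(theta[seq_len(d)]); lSe <- exp(theta[d + seq_len(d)])
  sigma2 <- exp(theta[2 * d + 1]); noise <- exp(theta[2 * d + 2])
  Kf <- lpKernelFromPre(pre, lPer, lSe, sigma2)
  fac <- cholWithJitter(Kf, noise)  # may signal torsbo_conditioning_error
  alpha <- backsolve(fac$L, forwardsolve(t(fac$L), nz$yn))
  new("GPTorsionModel", X = X, y = y, periodicities = periodicities,
      params = list(lPer = lPer, lSe = lSe, sigma2 = sigma2, noise = noise),
      circularSE = circularSE, L = fac$L, alpha = alpha,
      yMean = nz$mean, ySd = nz$sd, jitter = fac$jitter)
}

# lean single-point predictor closure for inner-loop optimization: same
# math as the predict method without S4 dispatch or matrix packaging
gpPredictor <- function(model) {
  p <- model@params
  periods <- 2 * pi / model@periodicities
  X <- model@X
  Lt <- t(model@L)
  alpha <- model@alpha
  d <- ncol(X)
  circ <- model@circularSE
  yM <- model@yMean; yS <- model@ySd
  function(th) {
    logk <- 0
    for (i in seq_len(d)) {
      D <- th[i] - X[, i]
      s2 <- sin(pi * D / periods[i])^2
      r <- if (circ) {
        a <- abs(D) %% (2 * pi)
        2 * sin(pmin(a, 2 * pi - a) / 2)
      } else abs(D)
      logk <- logk - 2 * s2 / p$lPer[i]^2 - r * r / (2 * p$lSe[i]^2)
    }
    k <- p$sigma2 * exp(logk)
    v <- forwardsolve(Lt, k)
    c(mean = yM + yS * sum(k * alpha),
      var = yS^2 * max(p$sigma2 - sum(v * v), 0))
  }
}

#' Posterior mean and variance of the surrogate
#'
#' Standard GP conditionals, denormalized back to raw energy units. The
#' posterior variance is clamped at zero against roundoff.
#'
#' @param object a [GPTorsionModel-class].
#' @param newdata matrix of query torsion vectors (rows), or a single vector.
#' @param ... ignored.
#' @return list with numeric vectors `mean` (kcal/mol scale of the training
#'   outputs) and `var`.
#' @export
setMethod("predict", "GPTorsionModel", function(object, newdata, ...) {
  Xq <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  if (ncol(Xq) != ncol(object@X))
    stop("query dimension ", ncol(Xq), " does not match the model dimension ",
         ncol(object@X), call. = FALSE)
  p <- object@params
  periods <- 2 * pi / object@periodicities
  Ks <- lpKernelMatrix(Xq, object@X, p$lPer, p$lSe, p$sigma2, periods,
                       object@circularSE)
  mu <- as.numeric(Ks %*% object@alpha)
  V <- forwardsolve(t(object@L), t(Ks))
  var <- pmax(p$sigma2 - colSums(V^2), 0)
  list(mean = object@yMean + object@ySd * mu, var = object@ySd^2 * var)
})
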
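# Kernels and Gaussian-process regression on the torsion hypercube.

test_that("kernel closed forms hold", {
  expect_equal(kSE(1.3, 1.3, l = 0.7, sigma2 = 2.5), 2.5)
  # wrapped-distance form: r = l*sqrt(2) forces exp(-1)
  l <- 0.4
  expect_equal(kSE(0, l * sqrt(2), l = l, distance = "wrapped"), exp(-1),
               tolerance = 1e-12)
  # wraparound: 0 and 2*pi - eps are close on the circle
  expect_gt(kSE(0, 2 * pi - 1e-8, l = 1), 1 - 1e-8)

  expect_equal(kPer(0.3, 0.3 + pi / 2, l = 2, p = pi / 2, sigma2 = 3), 3)
  expect_equal(kPer(0, pi / 4, l = 1, p = pi / 2), exp(-2), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:10) {
    x <- runif(1, 0, 2 * pi); y <- runif(1, 0, 2 * pi)
    expect_equal(kPer(x, y, l = 0.8, p = pi), kPer(x + pi, y, l = 0.8, p = pi),
                 tolerance = 1e-12)
  }
})

test_that("locally periodic kernel: diagonal, 1-D reduction, PSD", {
  params <- list(lPer = 0.9, lSe = 1.7, sigma2 = 4, periods = c(pi, 2 * pi / 3))
  x <- c(1, 2)
  expect_equal(kLocallyPeriodic(x, x, params), 4)
  p1 <- list(lPer = 0.9, lSe = 1.7, sigma2 = 2, periods = pi)
  set.seed(2)
  for (i in 1:10) {
    a <- runif(1, 0, 2 * pi); b <- runif(1, 0, 2 * pi)
    expect_equal(kLocallyPeriodic(a, b, p1),
                 2 * kPer(a, b, l = 0.9, p = pi) * kSE(a, b, l = 1.7),
                 tolerance = 1e-12)
  }
  # eigendecomposition oracle on random point sets
  set.seed(3)
  X <- matrix(runif(20, 0, 2 * pi), ncol = 2)
  K <- outer(seq_len(10), seq_len(10), Vectorize(function(i, j)
    kLocallyPeriodic(X[i, ], X[j, ], params)))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
})

test_that("non-positive hyperparameters and dimension mismatches error", {
  expect_error(kSE(0, 1, l = 0), "positive")
  expect_error(kPer(0, 1, l = 1, p = -2), "positive")
  expect_error(kLocallyPeriodic(c(0, 1), 0.5,
                                list(lPer = 1, lSe = 1, sigma2 = 1,
                                     periods = c(pi, pi))), "equal length")
})

test_that("PSD property holds across 50 random torsion Gram matrices", {
  set.seed(17)
  for (rep in 1:50) {
    d <- sample(1:3, 1)
    X <- matrix(runif(12 * d, 0, 2 * pi), ncol = d)
    K <- torsbo:::lpKernelMatrix(X, X, runif(d, 0.05, 10), runif(d, 0.05, 10),
                                 1, 2 * pi / sample(1:3, d, TRUE))
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(ev))
  }
})

test_that("single-observation fit predicts its training value", {
  m <- fitGP(matrix(2.1, 1, 1), 7.5, periodicities = 2)
  pr <- predict(m, 2.1)
  expect_equal(pr$mean, 7.5, tolerance = 1e-9)
})

test_that("duplicate training rows fit through the jitter ladder", {
  X <- matrix(rep(c(1, 2), each = 4), ncol = 1)
  y <- c(1, 1, 1, 1, 3, 3, 3, 3)
  expect_no_error(m <- fitGP(X, y, periodicities = 1))
  pr <- predict(m, matrix(c(1, 2), ncol = 1))
  expect_equal(pr$mean, c(1, 3), tolerance = 0.2)
})

test_that("fitted hyperparameters beat random draws in marginal likelihood", {
  set.seed(5)
  X <- matrix(runif(24, 0, 2 * pi), ncol = 2)
  y <- sin(X[, 1]) + 0.3 * cos(3 * X[, 2]) + rnorm(12, sd = 0.05)
  per <- c(1, 3)
  m <- fitGP(X, y, periodicities = per)
  lmlFit <- gpLogMarginalLikelihood(X, y, per, m@params)
  b <- gpBounds()
  for (i in 1:20) {
    draw <- list(lPer = exp(runif(2, log(b$lengthScale[1]),
                                  log(b$lengthScale[2]))),
                 lSe = exp(runif(2, log(b$lengthScale[1]),
                                 log(b$lengthScale[2]))),
                 sigma2 = exp(runif(1, log(b$sigma2[1]), log(b$sigma2[2]))),
                 noise = exp(runif(1, log(b$noise[1]), log(b$noise[2]))))
    expect_gte(lmlFit, gpLogMarginalLikelihood(X, y, per, draw) - 1e-6)
  }
})

test_that("posterior interpolates with tiny noise and reverts to the prior", {
  set.seed(6)
  X <- matrix(runif(8, 0, 2 * pi), ncol = 1)
  y <- cos(2 * X[, 1])
  fixed <- list(lPer = 0.5, lSe = 1, sigma2 = 1, noise = 1e-6)
  m <- fitGP(X, y, periodicities = 2, warmStart = fixed, nStarts = 0,
             maxit = 0)
  pr <- predict(m, X)
  expect_lt(max(abs(pr$mean - y)), 1e-3)
  expect_lt(max(pr$var), 1e-3 * m@ySd^2)
  # far from all data (raw-distance SE, short length scales)
  mFar <- fitGP(matrix(c(0.1, 0.2), ncol = 1), c(5, 7), periodicities = 1,
                warmStart = list(lPer = 0.05, lSe = 0.05, sigma2 = 1,
                                 noise = 1e-6),
                nStarts = 0, maxit = 0, circularSE = FALSE)
  prFar <- predict(mFar, matrix(pi, 1, 1))
  expect_equal(prFar$mean, 6, tolerance = 1e-6)        # training mean
  expect_equal(prFar$var, mFar@ySd^2 * 1, tolerance = 1e-6)
})

test_that("predictions match the dense conditional-Gaussian oracle", {
  set.seed(7)
  for (rep in 1:5) {
    d <- sample(1:3, 1)
    n <- sample(3:20, 1)
    per <- sample(1:3, d, replace = TRUE)
    X <- matrix(runif(n * d, 0, 2 * pi), ncol = d)
    y <- rowSums(sin(sweep(X, 2, per, `*`))) + rnorm(n, sd = 0.1)
    fixed <- list(lPer = runif(1, 0.5, 2), lSe = runif(1, 1, 3),
                  sigma2 = runif(1, 0.5, 2), noise = 1e-2)
    m <- fitGP(X, y, per, warmStart = fixed, nStarts = 0, maxit = 0)
    q <- matrix(runif(4 * d, 0, 2 * pi), ncol = d)
    pr <- predict(m, q)
    # independent dense-matrix route
    p <- m@params
    periods <- 2 * pi / per
    kv <- function(a, b) {
      s <- sin(pi * (a - b) / periods)
      cd <- pmin(abs(a - b) %% (2 * pi), 2 * pi - abs(a - b) %% (2 * pi))
      p$sigma2 * exp(-sum(2 * s^2 / rep(p$lPer, length.out = d)^2) -
                     sum((2 * sin(cd / 2))^2 / (2 * rep(p$lSe, length.out = d)^2)))
    }
    K <- outer(1:n, 1:n, Vectorize(function(i, j) kv(X[i, ], X[j, ]))) +
      diag(p$noise + m@jitter, n)
    Ks <- outer(1:4, 1:n, Vectorize(function(i, j) kv(q[i, ], X[j, ])))
    yn <- (y - m@yMean) / m@ySd
    muO <- m@yMean + m@ySd * as.numeric(Ks %*% solve(K, yn))
    varO <- m@ySd^2 * (p$sigma2 - diag(Ks %*% solve(K, t(Ks))))
    expect_lt(max(abs(pr$mean - muO) / pmax(abs(muO), 1e-8)), 1e-8)
    expect_lt(max(abs(pr$var - varO) / pmax(abs(varO), 1e-8)), 1e-6)
  }
})

test_that("predictions are invariant to torus shifts by the kernel period", {
  set.seed(8)
  d <- 2; per <- c(2, 3); n <- 10
  X <- matrix(runif(n * d, 0, 2 * pi), ncol = d)
  y <- rnorm(n)
  fixed <- list(lPer = 1, lSe = 2, sigma2 = 1, noise = 1e-2)
  q <- matrix(runif(3 * d, 0, 2 * pi), ncol = d)
  m <- fitGP(X, y, per, warmStart = fixed, nStarts = 0, maxit = 0)
  pr <- predict(m, q)
  # shift every input (training and query) in one dimension by its period
  for (i in 1:d) {
    sh <- rep(0, d); sh[i] <- 2 * pi / per[i]
    m2 <- fitGP(sweep(X, 2, sh, `+`), y, per, warmStart = fixed,
                nStarts = 0, maxit = 0)
    pr2 <- predict(m2, sweep(q, 2, sh, `+`))
    expect_equal(pr2$mean, pr$mean, tolerance = 1e-10)
    expect_equal(pr2$var, pr$var, tolerance = 1e-10)
  }
  # a full 2*pi shift of a single training point changes nothing
  X3 <- X; X3[1, 1] <- X3[1, 1] + 2 * pi
  m3 <- fitGP(X3, y, per, warmStart = fixed, nStarts = 0, maxit = 0)
  pr3 <- predict(m3, q)
  expect_equal(pr3$mean, pr$mean, tolerance = 1e-10)
})

test_that("denormalized posterior means are affine-equivariant in y", {
  set.seed(9)
  X <- matrix(runif(14, 0, 2 * pi), ncol = 1)
  y <- sin(X[, 1])
  fixed <- list(lPer = 1, lSe = 2, sigma2 = 1, noise = 1e-3)
  q <- matrix(runif(5, 0, 2 * pi), ncol = 1)
  m1 <- fitGP(X, y, 1, warmStart = fixed, nStarts = 0, maxit = 0)
  a <- 3.7; b <- -11
  m2 <- fitGP(X, a * y + b, 1, warmStart = fixed, nStarts = 0, maxit = 0)
  expect_equal(predict(m2, q)$mean, a * predict(m1, q)$mean + b,
               tolerance = 1e-9)
})

test_that("the jitter ladder signals a conditioning error only when exhausted", {
  bad <- matrix(c(1, 2, 2, 1), 2)  # eigenvalues 3 and -1: beyond any jitter
  expect_error(torsbo:::cholWithJitter(bad, 1e-6),
               class = "torsbo_conditioning_error")
  dup <- matrix(1, 3, 3)           # PSD but singular: jitter rescues it
  expect_no_error(torsbo:::cholWithJitter(dup, 1e-6))
})
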
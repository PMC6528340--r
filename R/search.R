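#' @include acquisition.R objective.R
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default evaluation budget by flexibility
#'
#' 50 objective evaluations for molecules with three or fewer rotatable
#' bonds, 100 otherwise. Rigid molecules (0 rotors) still map to 50, but a
#' search over an empty hypercube is pointless and callers should skip it.
#'
#' @param nRotatable number of rotatable bonds (>= 0).
#' @return integer budget K.
#' @export
defaultBudget <- function(nRotatable) {
  stopifnot(nRotatable >= 0)
  ifelse(nRotatable <= 3, 50L, 100L)
}

#' Search configuration
#'
#' @param budget total number of objective evaluations K (`NULL`: use
#'   [defaultBudget()] for the problem dimension).
#' @param nInit initial uniform-random observations before the surrogate
#'   kicks in (BOA only).
#' @param acquisition an [acquisitionSpec()].
#' @param seed root seed for the run; `NULL` leaves the RNG state alone.
#' @param energyCutoff systematic search: discard conformers more than this
#'   many kcal/mol above the lowest energy seen.
#' @param dedupRMSD systematic search: RMSD threshold (Angstrom) under which
#'   a retained conformer counts as a duplicate.
#' @param maxConformers systematic search: enumeration cap.
#' @param refitDense refit GP hyperparameters every iteration while the
#'   training set has at most this many points, every 5 iterations beyond
#'   (the fit is cubic in the number of observations).
#' @return a validated list of class `"searchConfig"`.
#' @export
searchConfig <- function(budget = NULL, nInit = 5L,
                         acquisition = acquisitionSpec(), seed = NULL,
                         energyCutoff = 500, dedupRMSD = 0.05,
                         maxConformers = 1e6, refitDense = 50L) {
  stopifnot(nInit >= 1, energyCutoff >= 0, dedupRMSD >= 0, maxConformers >= 1)
  if (!is.null(budget) && budget <= nInit)
    stop("budget K must exceed the number of initial observations",
         call. = FALSE)
  structure(list(budget = budget, nInit = as.integer(nInit),
                 acquisition = acquisition, seed = seed,
                 energyCutoff = energyCutoff, dedupRMSD = dedupRMSD,
                 maxConformers = maxConformers,
                 refitDense = as.integer(refitDense)),
            class = "searchConfig")
}

evalObjective <- function(objective, theta) {
  val <- tryCatch(objective(theta), error = function(e) {
    stop(errorCondition(
      paste0("objective evaluation failed at torsion vector [",
             paste(sprintf("%.4f", theta), collapse = ", "), "]: ",
             conditionMessage(e)),
      class = c("torsbo_objective_error", "error"),
      torsions = theta))
  })
  as.numeric(val)
}

makeSearchResult <- function(method, thetas, energies, seed, termination,
                             objective, extra = list()) {
  best <- which.min(energies)
  conf <- NULL
  confFun <- attr(objective, "conformerFun")
  if (!is.null(confFun)) {
    conf <- confFun(thetas[best, ])
    conf@energy <- energies[best]
  }
  new("SearchResult", method = method, thetas = thetas, energies = energies,
      bestIndex = as.integer(best),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      termination = termination, conformer = conf, extra = extra)
}

#' Bayesian-optimization search over the torsion hypercube
#'
#' The core loop: draw `nInit` uniform random torsion vectors and evaluate
#' them, then repeat (refit surrogate, propose the acquisition optimum,
#' evaluate) until `K` total evaluations. Hyperparameters are refit every
#' iteration while the training set is small and every fifth iteration
#' afterwards. If the kernel matrix cannot be factorized even with maximal
#' jitter, the run stops early and returns the partial result flagged
#' `"early_stop"` so that benchmark harnesses can exclude it.
#'
#' @param objective function mapping a torsion vector (length `d`) to a
#'   finite energy; steric clashes should return large finite values.
#' @param d search dimension (number of rotatable bonds, >= 1).
#' @param periodicities integer periodicity per dimension.
#' @param config a [searchConfig()].
#' @param circularSE passed to [fitGP()].
#' @return a [SearchResult-class].
#' @examples
#' obj <- syntheticObjective(d = 1, periodicity = 2)
#' res <- boaSearch(obj, d = 1, periodicities = 2,
#'                  config = searchConfig(budget = 20, seed = 1))
#' bestEnergy(res)
#' @export
boaSearch <- function(objective, d, periodicities, config = searchConfig(),
                      circularSE = TRUE) {
  stopifnot(d >= 1, length(periodicities) == d)
  K <- config$budget %||% defaultBudget(d)
  if (!is.null(config$seed)) set.seed(config$seed)
  thetas <- matrix(stats::runif(config$nInit * d, 0, 2 * pi), ncol = d)
  energies <- vapply(seq_len(config$nInit), function(i)
    evalObjective(objective, thetas[i, ]), numeric(1))
  termination <- "budget"
  warm <- NULL
  model <- NULL
  i <- config$nInit
  while (i < K) {
    n <- nrow(thetas)
    refit <- is.null(model) || n <= config$refitDense ||
      (n - config$refitDense) %% 5L == 0L
    fitOrStop <- tryCatch({
      if (refit)
        model <- fitGP(thetas, energies, periodicities, warmStart = warm,
                       circularSE = circularSE)
      else
        model <- refreshGP(model, thetas, energies)
      warm <- model@params
      TRUE
    }, torsbo_conditioning_error = function(e) FALSE)
    if (!fitOrStop) { termination <- "early_stop"; break }
    thNext <- proposeNext(model, config$acquisition)
    eNext <- evalObjective(objective, thNext)
    thetas <- rbind(thetas, thNext)
    energies <- c(energies, eNext)
    i <- i + 1
  }
  rownames(thetas) <- NULL
  makeSearchResult(methodLabel("boa", config$acquisition), thetas, energies,
                   config$seed, termination, objective)
}

# refresh the cached decomposition with new data, keeping hyperparameters
refreshGP <- function(model, X, y) {
  fitGP(X, y, model@periodicities, nStarts = 0L, warmStart = model@params,
        circularSE = model@circularSE, maxit = 0L)
}

methodLabel <- function(prefix, spec) {
  paste0(prefix, "-", tolower(spec$kind))
}

#' Uniform random search
#'
#' Draws `K` i.i.d. torsion vectors uniformly on the hypercube and evaluates
#' all of them; the stochastic baseline.
#'
#' @inheritParams boaSearch
#' @return a [SearchResult-class].
#' @export
uniformSearch <- function(objective, d, config = searchConfig()) {
  stopifnot(d >= 1)
  K <- config$budget %||% defaultBudget(d)
  if (!is.null(config$seed)) set.seed(config$seed)
  thetas <- matrix(stats::runif(K * d, 0, 2 * pi), ncol = d)
  energies <- vapply(seq_len(K), function(i)
    evalObjective(objective, thetas[i, ]), numeric(1))
  makeSearchResult("uniform", thetas, energies, config$seed, "budget",
                   objective)
}

#' Systematic torsion driving
#'
#' Enumerates the Cartesian product of per-bond angle grids (the
#' deterministic baseline in the spirit of torsion-driving enumerators).
#' Conformers more than `energyCutoff` kcal/mol above the lowest energy seen
#' are discarded (re-filtered at the end against the final minimum), and
#' retained conformers closer than `dedupRMSD` to an already-kept one are
#' dropped as duplicates. Without geometry (`objective` lacking a conformer
#' generator), deduplication falls back to exact torsion-vector identity.
#'
#' @inheritParams boaSearch
#' @param angleSets list of allowed angles (radians) per bond; `NULL` uses
#'   `2 * periodicity` evenly spaced angles per bond.
#' @param periodicities required when `angleSets` is `NULL`.
#' @return a [SearchResult-class]; `extra` holds `retained` (indices into
#'   the trace) and `enumerated` (the full enumeration size before capping).
#' @export
systematicSearch <- function(objective, d, angleSets = NULL,
                             config = searchConfig(), periodicities = NULL) {
  stopifnot(d >= 1)
  if (is.null(angleSets)) {
    if (is.null(periodicities))
      stop("either angleSets or periodicities must be given")
    angleSets <- lapply(periodicities, function(p) {
      k <- 2L * p
      2 * pi * (seq_len(k) - 1) / k
    })
  }
  stopifnot(length(angleSets) == d)
  sizes <- vapply(angleSets, length, integer(1))
  total <- prod(sizes)
  nEval <- min(total, config$maxConformers)
  if (total > config$maxConformers)
    warning("enumeration size ", total, " exceeds the cap of ",
            config$maxConformers, "; only the first ", nEval,
            " conformers are evaluated", call. = FALSE)
  grid <- as.matrix(expand.grid(angleSets, KEEP.OUT.ATTRS = FALSE))
  dimnames(grid) <- NULL
  grid <- grid[seq_len(nEval), , drop = FALSE]
  energies <- vapply(seq_len(nEval), function(i)
    evalObjective(objective, grid[i, ]), numeric(1))
  # relative energy cutoff against the final minimum
  keep <- which(energies <= min(energies) + config$energyCutoff)
  confFun <- attr(objective, "conformerFun")
  retained <- integer(0)
  keptCoords <- list()
  for (i in keep) {
    dup <- FALSE
    if (!is.null(confFun) && config$dedupRMSD > 0) {
      ci <- confFun(grid[i, ])
      for (kc in keptCoords) {
        if (conformerRMSD(ci, kc) < config$dedupRMSD) { dup <- TRUE; break }
      }
      if (!dup) keptCoords[[length(keptCoords) + 1]] <- ci
    } else {
      for (j in retained) {
        if (all(grid[i, ] == grid[j, ])) { dup <- TRUE; break }
      }
    }
    if (!dup) retained <- c(retained, i)
  }
  makeSearchResult("systematic", grid, energies, config$seed, "budget",
                   objective,
                   extra = list(retained = retained, enumerated = total))
}

#' Run a search method on a molecule
#'
#' Convenience wrapper tying the MMFF94 objective to the three strategies.
#'
#' @param mol a [TorsionMolecule-class] with at least one rotatable bond.
#' @param method `"boa-ei"`, `"boa-lcb"`, `"boa-pi"`, `"uniform"` or
#'   `"systematic"`.
#' @param config a [searchConfig()].
#' @param ... passed to the underlying search function.
#' @return a [SearchResult-class] whose best conformer carries coordinates
#'   and energy.
#' @export
searchMolecule <- function(mol, method = c("boa-ei", "boa-lcb", "boa-pi",
                                           "uniform", "systematic"),
                           config = searchConfig(), ...) {
  method <- match.arg(method)
  d <- nRotors(mol)
  if (d == 0) stop("molecule '", mol@name, "' has no rotatable bonds")
  obj <- mmff94Objective(mol)
  per <- periodicities(mol)
  switch(method,
    "boa-ei" = {
      config$acquisition$kind <- "EI"
      boaSearch(obj, d, per, config, ...)
    },
    "boa-lcb" = {
      config$acquisition$kind <- "LCB"
      boaSearch(obj, d, per, config, ...)
    },
    "boa-pi" = {
      config$acquisition$kind <- "PI"
      boaSearch(obj, d, per, config, ...)
    },
    uniform = uniformSearch(obj, d, config),
    systematic = systematicSearch(obj, d, config = config,
                                  periodicities = per, ...)
  )
}
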
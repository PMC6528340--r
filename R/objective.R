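#' @include torsions.R
NULL

#' MMFF94 single-point objective for a molecule
#'
#' Returns a closure mapping a torsion vector to the fixed-rotor MMFF94
#' energy (kcal/mol): the molecule's rotatable bonds are driven to the
#' requested angles and a single-point energy is computed with Open Babel's
#' MMFF94 implementation — no geometry optimization, so bond lengths, bond
#' angles and rings keep their reference values. Clashing geometries simply
#' return their (large, finite) energies; no capping is applied.
#'
#' The returned function carries a `conformerFun` attribute mapping a
#' torsion vector to the corresponding [Conformer-class], which search
#' drivers use to attach geometry to their results, and a `forcefield`
#' attribute recording the implementation (absolute energies differ between
#' MMFF94 flavors and toolkits).
#'
#' @param mol a [TorsionMolecule-class].
#' @param forcefield force-field name understood by Open Babel (default
#'   `"MMFF94"`; `"MMFF94s"` is the static variant).
#' @return function(theta) -> energy in kcal/mol.
#' @seealso [mmff94Energy()] for one-shot evaluation.
#' @export
mmff94Objective <- function(mol, forcefield = "MMFF94") {
  obmol <- obmolFromSDFText(moleculeToSDFText(mol))
  ff <- obFindForceField(forcefield)
  # fail fast on parameterization problems at the reference geometry
  obSinglePointEnergy(obmol, ff, forcefield)
  fn <- function(theta) {
    cf <- applyTorsions(mol, theta)
    obSetCoords(obmol, cf@coords)
    obSinglePointEnergy(obmol, ff, forcefield)
  }
  attr(fn, "conformerFun") <- function(theta) applyTorsions(mol, theta)
  attr(fn, "forcefield") <- forcefield
  fn
}

#' One-shot MMFF94 single-point energy
#'
#' @param mol a [TorsionMolecule-class].
#' @param theta torsion vector; defaults to the reference torsions, in which
#'   case the energy equals the toolkit's direct single-point energy of the
#'   reference coordinates.
#' @param forcefield see [mmff94Objective()].
#' @return energy in kcal/mol.
#' @export
mmff94Energy <- function(mol, theta = measureTorsions(mol),
                         forcefield = "MMFF94") {
  mmff94Objective(mol, forcefield)(theta)
}

#' Synthetic torsional potential with known minimum
#'
#' A separable cosine landscape standing in for a force-field torsion
#' profile in tests and calibration runs:
#' `E(theta) = sum_i A_i (1 - cos(p_i (theta_i - phi_i)))
#'  + c * sum_{i<j} cos(theta_i - theta_j) + noise`.
#' With `coupling = 0` and `noise = 0` the global minimum is analytic:
#' value 0 attained at `theta_i = phi_i (mod 2*pi/p_i)`, exposed through the
#' `trueMinimum` and `trueValue` attributes.
#'
#' @param d dimension.
#' @param periodicity integer periodicities (recycled to length `d`).
#' @param amplitude per-dimension amplitudes `A_i > 0` (recycled).
#' @param phase per-dimension phases in `[0, 2*pi)` (recycled).
#' @param coupling pairwise coupling strength `c >= 0`.
#' @param noise observation noise standard deviation.
#' @param seed optional seed for the noise stream only; the noise draws use
#'   a private RNG state so evaluation order does not perturb callers.
#' @return function(theta) -> energy, with attributes `spec`, and (when the
#'   minimum is analytic) `trueMinimum`, `trueValue`.
#' @export
syntheticObjective <- function(d, periodicity = 3, amplitude = 1, phase = 0,
                               coupling = 0, noise = 0, seed = NULL) {
  stopifnot(d >= 1, coupling >= 0, noise >= 0)
  p <- rep(as.integer(periodicity), length.out = d)
  A <- rep(amplitude, length.out = d)
  phi <- wrapAngle(rep(phase, length.out = d))
  stopifnot(all(A > 0), all(p >= 1))
  noiseEnv <- new.env()
  noiseEnv$state <- if (!is.null(seed)) seed else 0L
  fn <- function(theta) {
    stopifnot(length(theta) == d)
    e <- sum(A * (1 - cos(p * (theta - phi))))
    if (coupling > 0 && d > 1) {
      cp <- 0
      for (i in seq_len(d - 1))
        for (j in (i + 1):d) cp <- cp + cos(theta[i] - theta[j])
      e <- e + coupling * cp
    }
    if (noise > 0) {
      noiseEnv$state <- noiseEnv$state + 1L
      e <- e + noise * localNorm(noiseEnv$state)
    }
    e
  }
  attr(fn, "spec") <- list(d = d, periodicity = p, amplitude = A, phase = phi,
                           coupling = coupling, noise = noise, seed = seed)
  if (coupling == 0 && noise == 0) {
    attr(fn, "trueMinimum") <- phi
    attr(fn, "trueValue") <- 0
  }
  fn
}

# one N(0,1) draw from a private stream, leaving the caller's RNG untouched
localNorm <- function(counter) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(counter)
  stats::rnorm(1)
}

#' An ensemble of random synthetic potentials
#'
#' Draws `n` independent separable cosine potentials for calibration and
#' benchmarking of the search strategies: dimensions cycle through `dims`,
#' periodicities are sampled from {2, 3} (the common torsional
#' multiplicities), amplitudes from U[0.5, 2] kcal/mol, phases uniformly on
#' the circle; no coupling, no noise, so every potential has a known minimum
#' of 0.
#'
#' @param n number of potentials.
#' @param dims dimensions to cycle through.
#' @param seed RNG seed for drawing the ensemble.
#' @return list of objective functions as from [syntheticObjective()].
#' @export
syntheticEnsemble <- function(n = 20, dims = c(2, 3), seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    d <- dims[(i - 1) %% length(dims) + 1]
    syntheticObjective(
      d = d,
      periodicity = sample(c(2L, 3L), d, replace = TRUE),
      amplitude = stats::runif(d, 0.5, 2),
      phase = stats::runif(d, 0, 2 * pi))
  })
}
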
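#' @include AllGenerics.R
NULL

# ---- TorsionMolecule --------------------------------------------------------

#' TorsionMolecule: a small molecule with one reference conformer
#'
#' Container for the torsional search problem: the molecular graph (elements,
#' bonds with order and ring membership, hybridization labels), one set of
#' reference 3D coordinates in Angstrom, and the perceived rotatable bonds
#' with their kernel periodicities. Bond lengths, bond angles and ring systems
#' are frozen at the reference geometry; conformers differ only in the
#' dihedral angles about the rotatable bonds.
#'
#' The `rotors` slot is a data.frame with one row per rotatable bond and
#' columns `a`, `b`, `c`, `d` (the dihedral quadruple; `b`-`c` is the bond
#' axis), `periodicity`, `hybPair` and `pattern` (matched SMARTS record or
#' `"fallback"`).
#'
#' @slot name single molecule identifier.
#' @slot atoms data.frame with columns `elem` (element symbol) and `hyb`
#'   (one of `"sp"`, `"sp2"`, `"sp3"`, `"other"`).
#' @slot bonds data.frame with columns `a1`, `a2` (1-based atom indices),
#'   `order` (integer bond order; aromatic Kekule orders as read) and
#'   `inRing` (logical).
#' @slot coords numeric matrix (atoms x 3), Angstrom.
#' @slot rotors data.frame of rotatable bonds (see Details).
#'
#' @seealso [readMolecule()], [findRotatableBonds()], [applyTorsions()]
#' @export
setClass("TorsionMolecule",
  slots = c(
    name = "character",
    atoms = "data.frame",
    bonds = "data.frame",
    coords = "matrix",
    rotors = "data.frame"
  )
)

setValidity("TorsionMolecule", function(object) {
  msg <- character()
  n <- nrow(object@atoms)
  if (!all(c("elem", "hyb") %in% names(object@atoms)))
    msg <- c(msg, "atoms must have columns 'elem' and 'hyb'")
  if (nrow(object@coords) != n || ncol(object@coords) != 3)
    msg <- c(msg, "coords must be an atoms x 3 matrix")
  if (n > 0 && !all(is.finite(object@coords)))
    msg <- c(msg, "coords must be finite")
  if (nrow(object@bonds) > 0) {
    if (!all(c("a1", "a2", "order", "inRing") %in% names(object@bonds)))
      msg <- c(msg, "bonds must have columns a1, a2, order, inRing")
    else {
      idx <- c(object@bonds$a1, object@bonds$a2)
      if (any(idx < 1 | idx > n))
        msg <- c(msg, "bond atom indices out of range")
      else {
        # ring membership must agree with the bond graph (a bond is in a
        # ring iff it is not a bridge)
        ring <- ringBondFlags(object@bonds, n)
        if (!identical(ring, object@bonds$inRing))
          msg <- c(msg, "inRing flags inconsistent with the bond graph")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

# a bond lies in a ring iff it is not a bridge of the molecular graph
ringBondFlags <- function(bonds, nAtoms) {
  if (nrow(bonds) == 0) return(logical(0))
  g <- igraph::graph_from_edgelist(cbind(bonds$a1, bonds$a2), directed = FALSE)
  if (igraph::vcount(g) < nAtoms)
    g <- igraph::add_vertices(g, nAtoms - igraph::vcount(g))
  br <- igraph::bridges(g)
  flags <- rep(TRUE, nrow(bonds))
  flags[as.integer(br)] <- FALSE
  flags
}

# ---- Conformer --------------------------------------------------------------

#' Conformer: one torsional state of a TorsionMolecule
#'
#' Coordinates produced by driving the parent molecule's rotatable bonds to a
#' torsion vector under the fixed-rotor convention (bond lengths, bond angles
#' and ring systems unchanged). The energy slot stays `NA` until an objective
#' has evaluated the geometry.
#'
#' @slot molecule the parent [TorsionMolecule-class].
#' @slot coords numeric matrix (atoms x 3), Angstrom.
#' @slot torsions numeric vector in `[0, 2*pi)`, one angle per rotatable bond.
#' @slot energy numeric scalar (kcal/mol) or `NA`.
#' @export
setClass("Conformer",
  slots = c(
    molecule = "TorsionMolecule",
    coords = "matrix",
    torsions = "numeric",
    energy = "numeric"
  ),
  prototype = list(energy = NA_real_)
)

setValidity("Conformer", function(object) {
  msg <- character()
  if (!identical(dim(object@coords), dim(object@molecule@coords)))
    msg <- c(msg, "coords must match the parent molecule's dimensions")
  if (length(object@torsions) != nrow(object@molecule@rotors))
    msg <- c(msg, "torsions length must equal the rotatable-bond count")
  if (length(object@torsions) &&
      (any(object@torsions < 0) || any(object@torsions >= 2 * pi)))
    msg <- c(msg, "torsions must be wrapped into [0, 2*pi)")
  if (length(object@energy) != 1)
    msg <- c(msg, "energy must be a single value (possibly NA)")
  if (length(msg)) msg else TRUE
})

# ---- GPTorsionModel ---------------------------------------------------------

#' GPTorsionModel: Gaussian-process surrogate on the torsion hypercube
#'
#' A fitted GP with a locally periodic product kernel (per-dimension periodic
#' times squared-exponential factors, periods fixed from chemistry). Outputs
#' are normalized internally; predictions are returned in raw energy units.
#'
#' @slot X training inputs, n x d matrix of torsion vectors (radians).
#' @slot y raw training outputs (energies, kcal/mol).
#' @slot periodicities integer periodicity per dimension (kernel period is
#'   `2*pi / periodicity`).
#' @slot params list with elements `lPer`, `lSe` (length-d), `sigma2`,
#'   `noise` (scalars, normalized units).
#' @slot circularSE logical; use the wrapped circular distance in the SE
#'   factor (default) or the raw distance.
#' @slot L upper-triangular Cholesky factor of `K + (noise + jitter) I`.
#' @slot alpha solve of the decomposed system against normalized outputs.
#' @slot yMean,ySd normalization constants of the raw outputs.
#' @slot jitter diagonal jitter added to achieve a positive-definite factor.
#' @export
setClass("GPTorsionModel",
  slots = c(
    X = "matrix",
    y = "numeric",
    periodicities = "numeric",
    params = "list",
    circularSE = "logical",
    L = "matrix",
    alpha = "numeric",
    yMean = "numeric",
    ySd = "numeric",
    jitter = "numeric"
  )
)

setValidity("GPTorsionModel", function(object) {
  msg <- character()
  n <- nrow(object@X)
  if (n < 1) msg <- c(msg, "at least one training observation is required")
  if (length(object@y) != n) msg <- c(msg, "y length must equal nrow(X)")
  if (length(object@periodicities) != ncol(object@X))
    msg <- c(msg, "one periodicity per input dimension is required")
  if (any(object@periodicities < 1))
    msg <- c(msg, "periodicities must be >= 1")
  p <- object@params
  if (!all(c("lPer", "lSe", "sigma2", "noise") %in% names(p)))
    msg <- c(msg, "params must contain lPer, lSe, sigma2, noise")
  else if (any(unlist(p) <= 0))
    msg <- c(msg, "all kernel hyperparameters must be strictly positive")
  if (length(msg)) msg else TRUE
})

# ---- SearchResult -----------------------------------------------------------

#' SearchResult: the evaluation trace of one search run
#'
#' @slot method label, e.g. `"boa-ei"`, `"boa-lcb"`, `"uniform"`,
#'   `"systematic"`.
#' @slot thetas matrix of evaluated torsion vectors (one row per evaluation).
#' @slot energies raw objective values, same order as `thetas`.
#' @slot bestIndex index of the lowest energy in the trace.
#' @slot seed root seed of the run (`NA` if none was set).
#' @slot termination `"budget"` or `"early_stop"`.
#' @slot conformer best [Conformer-class] if the objective carries geometry,
#'   else `NULL`.
#' @slot extra method-specific details (systematic search: retained ensemble).
#' @export
setClass("SearchResult",
  slots = c(
    method = "character",
    thetas = "matrix",
    energies = "numeric",
    bestIndex = "integer",
    seed = "integer",
    termination = "character",
    conformer = "ANY",
    extra = "list"
  ),
  prototype = list(conformer = NULL, extra = list(),
                   termination = "budget", seed = NA_integer_)
)

setValidity("SearchResult", function(object) {
  msg <- character()
  if (length(object@energies) != nrow(object@thetas))
    msg <- c(msg, "one energy per evaluated torsion vector is required")
  if (length(object@energies) > 0) {
    if (object@bestIndex < 1 || object@bestIndex > length(object@energies))
      msg <- c(msg, "bestIndex out of range")
    else if (abs(object@energies[object@bestIndex] -
                 min(object@energies)) > 1e-12)
      msg <- c(msg, "bestIndex must point at the minimum of the trace")
  }
  if (!object@termination %in% c("budget", "early_stop"))
    msg <- c(msg, "termination must be 'budget' or 'early_stop'")
  if (length(msg)) msg else TRUE
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "TorsionMolecule", function(object) {
  cat(sprintf("TorsionMolecule '%s': %d atoms, %d bonds, %d rotatable\n",
              object@name, nrow(object@atoms), nrow(object@bonds),
              nrow(object@rotors)))
  if (nrow(object@rotors) > 0) {
    r <- object@rotors
    cat(sprintf("  rotor %d: axis %d-%d (quadruple %d-%d-%d-%d), p=%d [%s]\n",
                seq_len(nrow(r)), r$b, r$c, r$a, r$b, r$c, r$d,
                r$periodicity, r$pattern), sep = "")
  }
  invisible(NULL)
})

setMethod("show", "Conformer", function(object) {
  e <- if (is.na(object@energy)) "unevaluated" else
    sprintf("%.4f kcal/mol", object@energy)
  cat(sprintf("Conformer of '%s': torsions [%s] rad, energy %s\n",
              object@molecule@name,
              paste(sprintf("%.3f", object@torsions), collapse = ", "), e))
  invisible(NULL)
})

setMethod("show", "GPTorsionModel", function(object) {
  cat(sprintf(paste0(
    "GPTorsionModel: n=%d, d=%d, sigma2=%.3g, noise=%.3g, jitter=%.1g\n",
    "  periodicities: %s\n"),
    nrow(object@X), ncol(object@X), object@params$sigma2,
    object@params$noise, object@jitter,
    paste(object@periodicities, collapse = ", ")))
  invisible(NULL)
})

setMethod("show", "SearchResult", function(object) {
  cat(sprintf("SearchResult [%s]: %d evaluations, best %.4f (termination: %s)\n",
              object@method, length(object@energies),
              bestEnergy(object), object@termination))
  invisible(NULL)
})

# ---- accessors --------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("atomCoords", "TorsionMolecule", function(object, ...) object@coords)

#' @rdname accessors
#' @export
setMethod("atomCoords", "Conformer", function(object, ...) object@coords)

#' @rdname accessors
#' @export
setMethod("torsions", "Conformer", function(object, ...) object@torsions)

#' @rdname accessors
#' @export
setMethod("energy", "Conformer", function(object, ...) object@energy)

#' @rdname accessors
#' @export
setMethod("rotatableBonds", "TorsionMolecule", function(object, ...)
  object@rotors)

#' @rdname accessors
#' @export
setMethod("nRotors", "TorsionMolecule", function(object, ...)
  nrow(object@rotors))

#' @rdname accessors
#' @export
setMethod("periodicities", "TorsionMolecule", function(object, ...)
  object@rotors$periodicity)

#' @rdname accessors
#' @export
setMethod("periodicities", "GPTorsionModel", function(object, ...)
  object@periodicities)

#' @rdname accessors
#' @export
setMethod("bestEnergy", "SearchResult", function(object, ...)
  object@energies[object@bestIndex])

#' @rdname accessors
#' @export
setMethod("bestTorsions", "SearchResult", function(object, ...)
  object@thetas[object@bestIndex, ])

#' @rdname accessors
#' @export
setMethod("bestConformer", "SearchResult", function(object, ...)
  object@conformer)

#' @rdname accessors
#' @param degrees logical; report torsions in degrees instead of radians.
#' @export
setMethod("searchTrace", "SearchResult", function(object, degrees = FALSE, ...) {
  th <- object@thetas
  if (degrees) th <- radToDeg(th)
  d <- ncol(th)
  colnames(th) <- paste0("theta_", seq_len(max(d, 0)))
  data.frame(iteration = seq_along(object@energies), th,
             energy_kcal_mol = object@energies,
             best_so_far = cummin(object@energies))
})
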
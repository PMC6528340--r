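#' @include utils-angles.R
NULL

#' Accessor generics
#'
#' Small accessor layer over the package's S4 classes: atom coordinates,
#' torsion vectors, energies, rotatable-bond tables, and search traces.
#'
#' @param object an object of one of the package's S4 classes.
#' @param ... further arguments for methods.
#' @return see the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atomCoords", function(object, ...) standardGeneric("atomCoords"))

#' @rdname accessors
#' @export
setGeneric("torsions", function(object, ...) standardGeneric("torsions"))

#' @rdname accessors
#' @export
setGeneric("energy", function(object, ...) standardGeneric("energy"))

#' @rdname accessors
#' @export
setGeneric("rotatableBonds", function(object, ...) standardGeneric("rotatableBonds"))

#' @rdname accessors
#' @export
setGeneric("nRotors", function(object, ...) standardGeneric("nRotors"))

#' @rdname accessors
#' @export
setGeneric("bestEnergy", function(object, ...) standardGeneric("bestEnergy"))

#' @rdname accessors
#' @export
setGeneric("bestTorsions", function(object, ...) standardGeneric("bestTorsions"))

#' @rdname accessors
#' @export
setGeneric("bestConformer", function(object, ...) standardGeneric("bestConformer"))

#' @rdname accessors
#' @export
setGeneric("searchTrace", function(object, ...) standardGeneric("searchTrace"))

#' @rdname accessors
#' @export
setGeneric("periodicities", function(object, ...) standardGeneric("periodicities"))
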
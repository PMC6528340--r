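#' @include AllClasses.R
NULL

# Thin bridge to Open Babel through ChemmineOB's SWIG bindings. Everything
# here works on OBMol handles rebuilt on demand from SDF text; no external
# pointers are ever stored inside the package's S4 objects.

obNS <- function() getNamespace("ChemmineOB")

# parse one molecule from an SDF text block into an OBMol handle
obmolFromSDFText <- function(txt) {
  O <- obNS()
  if (length(txt) > 1) txt <- paste(txt, collapse = "\n")
  istr <- O$istreamFromString(txt)
  conv <- O$OBConversion(istr)
  if (!O$OBConversion_SetInFormat(conv, "SDF"))
    stop("Open Babel refused the SDF input format")
  mol <- O$OBMol()
  if (!O$OBConversion_Read(conv, mol))
    stop("Open Babel could not read the SDF block")
  mol
}

# per-atom hybridization labels from Open Babel (sp/sp2/sp3/other)
obHybridization <- function(obmol) {
  O <- obNS()
  n <- O$OBMol_NumAtoms(obmol)
  vapply(seq_len(n), function(i) {
    h <- O$OBAtom_GetHyb(O$OBMol_GetAtom(obmol, i))
    switch(as.character(h), "1" = "sp", "2" = "sp2", "3" = "sp3", "other")
  }, character(1))
}

#' All atom-mapped matches of a SMARTS pattern
#'
#' Runs an Open Babel SMARTS match and returns every (unique) hit as a vector
#' of 1-based atom indices in pattern-atom order.
#'
#' @param obmol an OBMol handle (internal).
#' @param smarts single SMARTS string.
#' @return list of integer vectors; empty list when nothing matches.
#' @keywords internal
smartsMatchAtoms <- function(obmol, smarts) {
  O <- obNS()
  sp <- O$OBSmartsPattern()
  if (!O$OBSmartsPattern_Init(sp, smarts))
    stop("malformed SMARTS pattern: '", smarts, "'",
         call. = FALSE)
  O$OBSmartsPattern_Match(sp, obmol)
  lapply(O$OBSmartsPattern_GetUMapList(sp), as.integer)
}

# push R-side coordinates into an existing OBMol
obSetCoords <- function(obmol, coords) {
  O <- obNS()
  for (i in seq_len(nrow(coords))) {
    O$OBAtom_SetVector(O$OBMol_GetAtom(obmol, i),
                       O$vector3(coords[i, 1], coords[i, 2], coords[i, 3]))
  }
  invisible(obmol)
}

# single-point force-field energy (kcal/mol for MMFF94) of the coordinates
# currently held by the OBMol; no geometry optimization is performed
obSinglePointEnergy <- function(obmol, ff, forcefield = "MMFF94") {
  O <- obNS()
  if (!O$OBForceField_Setup(ff, obmol)) {
    stop("force field '", forcefield, "' could not be set up for this ",
         "molecule (atom typing/parameterization failure)", call. = FALSE)
  }
  O$OBForceField_Energy(ff)
}

obFindForceField <- function(forcefield = "MMFF94") {
  O <- obNS()
  ff <- O$OBForceField_FindForceField(forcefield)
  if (is.null(ff)) stop("unknown force field: ", forcefield)
  ff
}
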
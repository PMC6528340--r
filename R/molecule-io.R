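#' @include openbabel.R
NULL

#' Read a molecule into a TorsionMolecule
#'
#' Accepts an SDF, MOL2 or SMILES file (recognized by extension
#' `.sdf`/`.mol`/`.mol2`/`.smi`), or a bare SMILES string. Inputs without 3D
#' coordinates (SMILES) are embedded with Open Babel's 3D builder; SDF and
#' MOL2 coordinates are taken as given and become the molecule's reference
#' conformer. Rotatable bonds are perceived immediately and periodicities
#' assigned from the hybridization fallback; call [assignPeriodicity()] with
#' a SMARTS library to refine them.
#'
#' @param input file path or SMILES string.
#' @param name optional molecule name; defaults to the file's title field.
#' @param ... passed on to [findRotatableBonds()].
#' @return a [TorsionMolecule-class].
#' @examples
#' \dontrun{
#' biphenyl <- readMolecule("c1ccccc1-c1ccccc1", name = "biphenyl")
#' nRotors(biphenyl)
#' }
#' @export
readMolecule <- function(input, name = NULL, ...) {
  stopifnot(is.character(input), length(input) == 1)
  if (file.exists(input)) {
    ext <- tolower(tools::file_ext(input))
    txt <- paste(readLines(input, warn = FALSE), collapse = "\n")
    sdfText <- switch(ext,
      sdf = , mol = txt,
      mol2 = ChemmineOB::convertFormat("MOL2", "SDF", txt),
      smi = , smiles = ChemmineOB::convertFormat(
        "SMI", "SDF", txt,
        options = data.frame(names = "gen3D", args = "")),
      stop("unrecognized molecule file extension: ", ext)
    )
  } else {
    src <- if (is.null(name)) input else paste(input, name)
    sdfText <- ChemmineOB::convertFormat(
      "SMI", "SDF", src, options = data.frame(names = "gen3D", args = ""))
  }
  moleculeFromSDFText(sdfText, name = name, ...)
}

# build a TorsionMolecule from one SDF text block
moleculeFromSDFText <- function(sdfText, name = NULL, ...) {
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  writeLines(sdfText, tmp)
  sdfset <- ChemmineR::read.SDFset(tmp)
  if (length(sdfset) < 1) stop("no molecule found in SDF input")
  moleculeFromSDF(sdfset[[1]], name = name, ...)
}

#' Build a TorsionMolecule from a ChemmineR SDF object
#'
#' @param sdf a `ChemmineR::SDF` object with 3D coordinates.
#' @param name optional molecule name.
#' @param ... passed on to [findRotatableBonds()].
#' @return a [TorsionMolecule-class].
#' @export
moleculeFromSDF <- function(sdf, name = NULL, ...) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(name)) {
    hdr <- ChemmineR::header(sdf)
    name <- if (nzchar(hdr[["Molecule_Name"]])) hdr[["Molecule_Name"]] else "mol"
  }
  elem <- sub("_.*$", "", rownames(ab))
  coords <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
  bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  bonds$inRing <- ringBondFlags(bonds, length(elem))
  # hybridization from Open Babel's perception of the same block
  obmol <- obmolFromSDFText(sdf2text(sdf))
  hyb <- obHybridization(obmol)
  hyb[elem == "H"] <- "other"
  mol <- new("TorsionMolecule", name = name,
             atoms = data.frame(elem = elem, hyb = hyb),
             bonds = bonds, coords = coords,
             rotors = emptyRotorTable())
  mol@rotors <- findRotatableBonds(mol, ...)
  assignPeriodicity(mol)
}

emptyRotorTable <- function() {
  data.frame(a = integer(0), b = integer(0), c = integer(0), d = integer(0),
             hybPair = character(0), periodicity = integer(0),
             pattern = character(0))
}

# render a ChemmineR SDF object (or build one from molecule data) as text
sdf2text <- function(sdf) paste(ChemmineR::sdf2str(sdf), collapse = "\n")

# assemble a ChemmineR SDF object from coordinates + molecule topology
moleculeToSDF <- function(mol, coords = mol@coords, datablock = character(0)) {
  n <- nrow(mol@atoms)
  nb <- nrow(mol@bonds)
  ab <- cbind(coords, matrix(0L, n, 12))
  colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:16))
  rownames(ab) <- paste(mol@atoms$elem, seq_len(n), sep = "_")
  bb <- cbind(mol@bonds$a1, mol@bonds$a2, mol@bonds$order,
              matrix(0L, nb, 4))
  colnames(bb) <- paste0("C", 1:7)
  rownames(bb) <- seq_len(nb)
  header <- c(Molecule_Name = mol@name, Source = "  torsbo", Comment = "",
              Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                    n, nb))
  new("SDF", header = header, atomblock = ab, bondblock = bb,
      datablock = datablock)
}

moleculeToSDFText <- function(mol, coords = mol@coords,
                              datablock = character(0)) {
  sdf2text(moleculeToSDF(mol, coords, datablock))
}

#' Write conformers to an SDF file
#'
#' Each conformer is written as one record with its energy in the
#' `E_MMFF94_kcal_mol` data tag and its torsion vector (radians,
#' comma-separated) in the `torsions_rad` tag.
#'
#' @param conformers a [Conformer-class] or list of conformers of one
#'   molecule.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeConformers <- function(conformers, file) {
  if (is(conformers, "Conformer")) conformers <- list(conformers)
  blocks <- vapply(conformers, function(cf) {
    tags <- c(E_MMFF94_kcal_mol = formatC(cf@energy, format = "f", digits = 6),
              torsions_rad = paste(formatC(cf@torsions, format = "f",
                                           digits = 8), collapse = ","))
    moleculeToSDFText(cf@molecule, cf@coords, datablock = tags)
  }, character(1))
  writeLines(blocks, file)
  invisible(file)
}
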
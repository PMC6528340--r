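# Shared fixtures. Molecules with real geometry come from the bundled SDF
# blocks (fixed coordinates, no 3D builder at test time); pure-graph toys
# are built directly so geometry is fully controlled.

fixtureMolecule <- local({
  cache <- new.env()
  function(name) {
    if (is.null(cache[[name]])) {
      path <- system.file("extdata", paste0(name, ".sdf"),
                          package = "torsbo", mustWork = TRUE)
      cache[[name]] <- readMolecule(path)
    }
    cache[[name]]
  }
})

# hand-built molecule: atoms/bonds/coords given explicitly
toyMolecule <- function(elem, hyb, bonds, coords, name = "toy") {
  bondsDf <- data.frame(a1 = bonds[, 1], a2 = bonds[, 2],
                        order = if (ncol(bonds) >= 3) bonds[, 3] else 1L)
  bondsDf$inRing <- torsbo:::ringBondFlags(bondsDf, length(elem))
  mol <- new("TorsionMolecule", name = name,
             atoms = data.frame(elem = elem, hyb = hyb),
             bonds = bondsDf, coords = coords,
             rotors = torsbo:::emptyRotorTable())
  mol@rotors <- findRotatableBonds(mol)
  assignPeriodicity(mol)
}

# a 4-carbon chain with ideal tetrahedral-ish geometry: one rotatable bond
toyButane <- function(dihedral = pi) {
  coords <- rbind(
    c(-1.5, 1.0, 0.0),
    c(-0.75, 0.0, 0.0),
    c(0.75, 0.0, 0.0),
    c(1.5, cos(pi - dihedral), sin(pi - dihedral)))
  toyMolecule(rep("C", 4), rep("sp3", 4),
              cbind(1:3, 2:4), coords, name = "toy-butane")
}

asConformer <- function(mol, coords = mol@coords) {
  new("Conformer", molecule = mol, coords = coords,
      torsions = measureTorsions(mol), energy = NA_real_)
}

bondLengths <- function(mol, coords) {
  sqrt(rowSums((coords[mol@bonds$a1, , drop = FALSE] -
                coords[mol@bonds$a2, , drop = FALSE])^2))
}

# all bond angles (j at the vertex) in radians
bondAngles <- function(mol, coords) {
  b <- mol@bonds
  adj <- lapply(seq_len(nrow(mol@atoms)), function(i)
    c(b$a2[b$a1 == i], b$a1[b$a2 == i]))
  out <- numeric(0)
  for (j in seq_along(adj)) {
    nb <- adj[[j]]
    if (length(nb) < 2) next
    for (ii in seq_len(length(nb) - 1)) for (jj in (ii + 1):length(nb)) {
      v1 <- coords[nb[ii], ] - coords[j, ]
      v2 <- coords[nb[jj], ] - coords[j, ]
      out <- c(out, acos(pmin(pmax(sum(v1 * v2) /
        sqrt(sum(v1^2) * sum(v2^2)), -1), 1)))
    }
  }
  out
}
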
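# Rotatable-bond perception, periodicity assignment, and torsion driving
# under the fixed-rotor convention.

test_that("rotatable bonds are perceived by the topological rule", {
  biphenyl <- fixtureMolecule("biphenyl")
  expect_equal(nRotors(biphenyl), 1)
  rot <- rotatableBonds(biphenyl)
  # the single rotor is the inter-ring bond: both axis atoms aromatic carbons
  expect_false(biphenyl@bonds$inRing[
    biphenyl@bonds$a1 == rot$b & biphenyl@bonds$a2 == rot$c])

  expect_equal(nRotors(fixtureMolecule("benzene")), 0)

  butane <- fixtureMolecule("butane")
  expect_equal(nRotors(butane), 1)
  rot <- rotatableBonds(butane)
  expect_setequal(c(rot$b, rot$c), c(2, 3))  # C2-C3; C1-C2/C3-C4 terminal
})

test_that("dihedral quadruples are valid and deterministic", {
  for (nm in c("biphenyl", "butane")) {
    mol <- fixtureMolecule(nm)
    rot <- rotatableBonds(mol)
    for (i in seq_len(nrow(rot))) {
      bonded <- function(u, v) any((mol@bonds$a1 == u & mol@bonds$a2 == v) |
                                   (mol@bonds$a1 == v & mol@bonds$a2 == u))
      expect_true(bonded(rot$a[i], rot$b[i]))
      expect_true(bonded(rot$c[i], rot$d[i]))
      expect_true(rot$a[i] != rot$d[i])
      expect_gte(rot$periodicity[i], 1)
    }
  }
})

test_that("perception is stable under atom reindexing", {
  mol <- toyButane()
  # reverse the atom order: 4-3-2-1
  perm <- 4:1
  inv <- order(perm)
  permuted <- toyMolecule(mol@atoms$elem[perm], mol@atoms$hyb[perm],
                          cbind(inv[mol@bonds$a1], inv[mol@bonds$a2]),
                          mol@coords[perm, ], name = "perm")
  r1 <- rotatableBonds(mol)
  r2 <- rotatableBonds(permuted)
  expect_equal(nrow(r1), nrow(r2))
  # the same physical bond, up to the permutation
  expect_setequal(inv[c(r1$b, r1$c)], c(r2$b, r2$c))
})

test_that("periodicity assignment: fallback and library first-match", {
  expect_equal(periodicities(fixtureMolecule("biphenyl")), 2)  # sp2-sp2
  expect_equal(periodicities(fixtureMolecule("butane")), 3)    # sp3-sp3

  butane <- fixtureMolecule("butane")
  lib <- data.frame(smarts = c("[CX4][CX4]", "[CX4][CX4]"),
                    periodicity = c(6L, 3L))
  withLib <- assignPeriodicity(butane, lib)
  expect_equal(periodicities(withLib), 6)  # first match wins
  expect_equal(rotatableBonds(withLib)$pattern, "[CX4][CX4]")
})

test_that("malformed periodicity libraries are rejected", {
  butane <- fixtureMolecule("butane")
  expect_error(assignPeriodicity(butane,
                                 data.frame(smarts = "[[[", periodicity = 2L)),
               "malformed SMARTS")
  expect_error(assignPeriodicity(butane,
                                 data.frame(smarts = "CC", periodicity = 0L)),
               "malformed")
  tmp <- withr::local_tempfile(lines = "CC no-tab-here")
  expect_error(readPeriodicityLibrary(tmp), "malformed")
})

test_that("apply/measure round-trips and leaves internal coordinates rigid", {
  mol <- readMolecule(system.file("extdata", "butane.sdf", package = "torsbo"))
  hexLike <- toyMolecule(rep("C", 6), rep("sp3", 6), cbind(1:5, 2:6),
                         cbind(seq(0, 5) * 1.2,
                               rep(c(0, 0.8), 3), rep(c(0, 0.1, 0.3), 2)),
                         name = "chain6")
  set.seed(421)
  for (m in list(mol, hexLike)) {
    d <- nRotors(m)
    bl0 <- bondLengths(m, m@coords)
    ba0 <- bondAngles(m, m@coords)
    for (rep in 1:50) {
      th <- runif(d, 0, 2 * pi)
      cf <- applyTorsions(m, th)
      expect_equal(measureTorsions(cf), th, tolerance = 1e-9)
      expect_lt(max(abs(bondLengths(m, cf@coords) - bl0)), 1e-6)
      expect_lt(max(abs(bondAngles(m, cf@coords) - ba0)), 1e-6)
    }
  }
})

test_that("driving to the current torsions is a no-op", {
  mol <- fixtureMolecule("biphenyl")
  cf <- applyTorsions(mol, measureTorsions(mol))
  expect_lt(max(abs(cf@coords - mol@coords)), 1e-9)
})

test_that("biphenyl at 0 versus pi differs only by the inter-ring dihedral", {
  mol <- fixtureMolecule("biphenyl")
  c0 <- applyTorsions(mol, 0)
  cp <- applyTorsions(mol, pi)
  expect_equal(abs(torsbo:::wrapToPi(measureTorsions(cp) -
                                     measureTorsions(c0))), pi,
               tolerance = 1e-9)
  expect_lt(max(abs(bondLengths(mol, c0@coords) -
                    bondLengths(mol, cp@coords))), 1e-9)
})

test_that("dimension mismatch and collinear geometry raise errors", {
  mol <- fixtureMolecule("butane")
  expect_error(applyTorsions(mol, c(1, 2)), "rotatable bonds")
  collinear <- toyMolecule(rep("C", 4), rep("sp3", 4), cbind(1:3, 2:4),
                           cbind(0:3, 0, 0), name = "linear")
  expect_error(measureTorsions(collinear), "collinear")
})

test_that("conformers round-trip through SDF with energy and torsion tags", {
  mol <- fixtureMolecule("butane")
  cf <- applyTorsions(mol, 1.25)
  cf@energy <- -12.345
  tmp <- withr::local_tempfile(fileext = ".sdf")
  writeConformers(cf, tmp)
  back <- ChemmineR::read.SDFset(tmp)
  expect_equal(length(back), 1)
  db <- ChemmineR::datablock(back[[1]])
  expect_equal(as.numeric(db[["E_MMFF94_kcal_mol"]]), -12.345,
               tolerance = 1e-6)
  expect_equal(as.numeric(strsplit(db[["torsions_rad"]], ",")[[1]]), 1.25,
               tolerance = 1e-6)
  reread <- moleculeFromSDF(back[[1]])
  expect_equal(measureTorsions(reread), 1.25, tolerance = 1e-4)
})
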
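# The evaluation layer: symmetry-aware RMSD, torsion fingerprint deviation,
# energy differences, signed-rank tests, benchmark summaries.

# brute-force automorphism enumeration for small graphs: all permutations
# preserving elements and adjacency (independent of the igraph route)
bruteAutomorphisms <- function(elem, bonds) {
  n <- length(elem)
  adj <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(bonds))) {
    adj[bonds[k, 1], bonds[k, 2]] <- TRUE
    adj[bonds[k, 2], bonds[k, 1]] <- TRUE
  }
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == n), ,
                 drop = FALSE]
  keep <- apply(perms, 1, function(p) {
    all(elem[p] == elem) && all(adj[p, p] == adj)
  })
  perms[keep, , drop = FALSE]
}

test_that("RMSD is zero for identical and symmetry-equivalent conformers", {
  bz <- fixtureMolecule("benzene")
  cf <- asConformer(bz)
  expect_equal(conformerRMSD(cf, cf), 0, tolerance = 1e-9)
  # flip 180 degrees about the C1-C4 twofold axis
  co <- atomCoords(bz)
  ax <- co[1, ] - co[4, ]; ax <- ax / sqrt(sum(ax^2))
  flipped <- torsbo:::rotateAbout(co, colMeans(co[1:6, ]), ax, pi)
  expect_equal(conformerRMSD(cf, asConformer(bz, flipped)), 0,
               tolerance = 1e-6)
})

test_that("the automorphism search discounts equivalent-atom relabelings", {
  # C1-C2-C3(=O4)(O5): the two oxygens are topologically equivalent, so
  # swapping their labels must not register as a geometric difference
  elem <- c("C", "C", "C", "O", "O")
  bonds <- cbind(c(1, 2, 3, 3), c(2, 3, 4, 5))
  co <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.3, 1.2, 0),
              c(1.8, 2.4, 0.3), c(3.6, 1.1, -0.4))
  mol <- toyMolecule(elem, c("sp3", "sp3", "sp2", "sp2", "sp2"), bonds, co,
                     name = "acid")
  swapped <- co[c(1, 2, 3, 5, 4), ]
  cfA <- new("Conformer", molecule = mol, coords = co,
             torsions = measureTorsions(mol), energy = NA_real_)
  cfB <- new("Conformer", molecule = mol, coords = swapped,
             torsions = measureTorsions(mol), energy = NA_real_)
  expect_equal(conformerRMSD(cfA, cfB), 0, tolerance = 1e-9)
  expect_gt(conformerRMSD(cfA, cfB, symmetry = FALSE), 0.3)
})

test_that("RMSD matches brute-force automorphism x superposition oracle", {
  # 5-atom toy: a C3 star with two O leaves (one automorphism swap)
  elem <- c("C", "C", "C", "O", "O")
  bonds <- cbind(c(1, 2, 2, 3), c(2, 3, 4, 5))
  coordsA <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.3, 1.2, 0),
                   c(2.1, -1.1, 0.4), c(3.6, 1.4, -0.2))
  coordsB <- coordsA + matrix(rnorm(15, sd = 0.15), 5)
  # rotate B arbitrarily: superposition must undo this
  R <- torsbo:::rotateAbout(coordsB, c(0, 0, 0), c(0, 0, 1), 1.1)
  mol <- toyMolecule(elem, rep("sp3", 5), bonds, coordsA, name = "star")
  cfA <- new("Conformer", molecule = mol, coords = coordsA,
             torsions = measureTorsions(mol), energy = NA_real_)
  cfB <- new("Conformer", molecule = mol, coords = R,
             torsions = measureTorsions(mol), energy = NA_real_)
  got <- conformerRMSD(cfA, cfB)
  perms <- bruteAutomorphisms(elem, bonds)
  oracle <- min(apply(perms, 1, function(p)
    torsbo:::kabschRMSD(coordsA, R[p, , drop = FALSE])))
  expect_equal(got, oracle, tolerance = 1e-9)
  # symmetric in its arguments
  expect_equal(conformerRMSD(cfB, cfA), got, tolerance = 1e-9)
  # widening the mapping set can only help
  expect_lte(got, conformerRMSD(cfA, cfB, symmetry = FALSE) + 1e-12)
})

test_that("TFD: zero on identical conformers, one at maximal deviation", {
  bu <- fixtureMolecule("butane")
  anti <- applyTorsions(bu, pi)
  syn <- applyTorsions(bu, 0)
  expect_equal(conformerTFD(anti, anti), 0)
  # single torsion differing by 180 degrees normalizes to exactly 1
  expect_equal(conformerTFD(anti, syn), 1, tolerance = 1e-9)
})

test_that("TFD stays within [0, 1] on random conformer pairs", {
  mol <- readMolecule(system.file("extdata", "butane.sdf",
                                  package = "torsbo"))
  chain <- toyMolecule(rep("C", 6), rep("sp3", 6), cbind(1:5, 2:6),
                       cbind(seq(0, 5) * 1.4, rep(c(0, 0.9), 3),
                             rep(c(0, 0.2, 0.5), 2)), name = "chain6")
  set.seed(30)
  for (m in list(mol, chain)) {
    for (i in 1:10) {
      c1 <- applyTorsions(m, runif(nRotors(m), 0, 2 * pi))
      c2 <- applyTorsions(m, runif(nRotors(m), 0, 2 * pi))
      v <- conformerTFD(c1, c2)
      expect_gte(v, 0); expect_lte(v, 1)
      expect_equal(conformerTFD(c2, c1), v, tolerance = 1e-12)
    }
  }
})

test_that("TFD errors on molecules without any usable torsion", {
  # two heavy atoms: no non-terminal acyclic bond, no ring
  ethane <- toyMolecule(c("C", "C"), c("sp3", "sp3"),
                        cbind(1, 2), rbind(c(0, 0, 0), c(1.5, 0, 0)),
                        name = "ethane")
  cf <- asConformer(ethane)
  expect_error(conformerTFD(cf, cf), class = "torsbo_no_torsions_error")
})

test_that("metrics vanish together only for equivalent conformations", {
  bu <- fixtureMolecule("butane")
  a <- applyTorsions(bu, 1.1)
  b <- applyTorsions(bu, 1.1 + 0.8)
  expect_gt(conformerRMSD(a, b), 1e-3)
  expect_gt(conformerTFD(a, b), 1e-3)
  expect_lt(conformerRMSD(a, applyTorsions(bu, 1.1)), 1e-9)
})

test_that("deltaE is a plain signed difference", {
  expect_equal(deltaE(5, 5), 0)
  expect_equal(deltaE(146.13, 146.04), 0.09, tolerance = 1e-9)
  expect_lt(deltaE(100, 101), 0)
})

test_that("exact Wilcoxon p-values match full sign-assignment enumeration", {
  x <- c(1.1, 2.3, 0.7, 4.1, 2.0, 3.3)
  y <- c(0.9, 2.9, 0.2, 3.0, 2.45, 3.14)  # distinct |differences|: no ties
  res <- pairedWilcoxon(x, y)
  expect_equal(res$method, "exact")
  # enumerate all 2^6 sign assignments of the ranked |differences|
  d <- x - y
  r <- rank(abs(d))
  Vobs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
  Vall <- signs %*% r
  pEnum <- mean(Vall >= max(Vobs, sum(r) - Vobs)) +
    mean(Vall <= min(Vobs, sum(r) - Vobs))
  expect_equal(res$p.value, pEnum, tolerance = 1e-12)
  # two-sided symmetry
  expect_equal(pairedWilcoxon(y, x)$p.value, res$p.value, tolerance = 1e-12)
})

test_that("degenerate and short inputs raise the insufficient-pairs error", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_error(pairedWilcoxon(x, x), class = "torsbo_insufficient_pairs_error")
  expect_error(pairedWilcoxon(1:4, c(2, 3, 4, 5) + 0.5),
               class = "torsbo_insufficient_pairs_error")
  expect_error(pairedWilcoxon(1:3, 1:4), "equal length")
})

test_that("exact and approximate branches agree to 0.02 at n = 25", {
  set.seed(31)
  for (rep in 1:5) {
    d <- rnorm(25) + 0.3
    x <- rnorm(25); y <- x - d
    dNz <- d[d != 0]
    r <- rank(abs(dNz))
    pExact <- stats::wilcox.test(dNz, exact = TRUE, correct = FALSE)$p.value
    pApprox <- stats::wilcox.test(dNz, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(pExact - pApprox), 0.02)
    # and the package picks the exact branch here
    expect_equal(pairedWilcoxon(x, y)$method, "exact")
  }
})

test_that("benchmark summaries match a hand-worked table", {
  records <- rbind(
    data.frame(molecule = "m1", nRotors = 2, method = "boa-ei",
               trial = 1:2, bestEnergy = c(10, 11), deltaE = c(-2, -1)),
    data.frame(molecule = "m1", nRotors = 2, method = "systematic",
               trial = 1, bestEnergy = 12, deltaE = 0),
    data.frame(molecule = "m2", nRotors = 2, method = "boa-ei",
               trial = 1:2, bestEnergy = c(21, 20), deltaE = c(1, 0)),
    data.frame(molecule = "m2", nRotors = 2, method = "systematic",
               trial = 1, bestEnergy = 20, deltaE = 0),
    data.frame(molecule = "m3", nRotors = 5, method = "boa-ei",
               trial = 1:2, bestEnergy = c(7, 7), deltaE = c(0, 0)),
    data.frame(molecule = "m3", nRotors = 5, method = "systematic",
               trial = 1, bestEnergy = 7, deltaE = 0))
  s <- summarizeBenchmark(records)
  g13 <- s[s$rotorGroup == "1-3" & s$method == "boa-ei", ]
  # trial 1 beats the baseline on m1 only (10 < 12, 21 > 20): 50%;
  # trial 2 likewise (11 < 12, 20 == 20): 50%
  expect_equal(g13$championRate, 50)
  # m1's LEC is 10 (hit in trial 1), m2's is 20 (hit in trial 2): 100%
  expect_equal(g13$lecRecovery, 100)
  expect_equal(g13$medianDeltaE, median(c(-2, -1, 1, 0)))
  # per-molecule max spread of per-trial bests: m1 -> 1, m2 -> 1
  expect_equal(g13$medianMaxVariation, 1)
  g5 <- s[s$rotorGroup == "5" & s$method == "boa-ei", ]
  expect_equal(g5$medianMaxVariation, 0)  # five identical trials
  expect_equal(g5$championRate, 0)
  base <- s[s$method == "systematic", ]
  expect_true(all(is.na(base$championRate)))
})
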
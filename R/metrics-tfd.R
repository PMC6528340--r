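#' @include metrics-rmsd.R
NULL

# Torsion fingerprint deviation machinery, following the published scheme of
# Schulz-Gasch, Hert, Fechner & Stahl (JCIM 2012): torsions of non-terminal
# acyclic bonds plus ring systems, each deviation normalized by the
# torsion's maximal possible deviation and weighted by topological distance
# from the most central bond.

# iterated neighborhood refinement on heavy atoms: equivalence classes that
# play the role of Morgan-style atom invariants (radius rounds of splitting)
atomInvariants <- function(mol, radius = 2L) {
  heavy <- which(mol@atoms$elem != "H")
  idx <- match(seq_len(nrow(mol@atoms)), heavy)
  b <- mol@bonds
  keep <- !is.na(idx[b$a1]) & !is.na(idx[b$a2])
  nb <- lapply(seq_along(heavy), function(i) integer(0))
  for (k in which(keep)) {
    i <- idx[b$a1[k]]; j <- idx[b$a2[k]]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  inv <- as.integer(factor(paste(mol@atoms$elem[heavy],
                                 lengths(nb), sep = ":")))
  for (r in seq_len(radius)) {
    keys <- vapply(seq_along(heavy), function(i)
      paste(inv[i], paste(sort(inv[nb[[i]]]), collapse = ","), sep = "|"),
      character(1))
    inv <- as.integer(factor(keys))
  }
  out <- rep(NA_integer_, nrow(mol@atoms))
  out[heavy] <- inv
  out
}

# atoms that cannot be central atoms of a torsion: in a triple bond, or
# allene-like centers with two double bonds
colinearAtomFlags <- function(mol) {
  flags <- rep(FALSE, nrow(mol@atoms))
  b <- mol@bonds
  flags[c(b$a1[b$order == 3], b$a2[b$order == 3])] <- TRUE
  dbl <- b[b$order == 2, , drop = FALSE]
  cnt <- table(c(dbl$a1, dbl$a2))
  flags[as.integer(names(cnt)[cnt >= 2])] <- TRUE
  flags
}

# non-ring, non-terminal torsion definitions with symmetric-neighbor
# handling: each entry is a list(quartets = matrix, maxDev)
tfdTorsionList <- function(mol, maxDev = c("equal", "spec")) {
  maxDev <- match.arg(maxDev)
  inv <- atomInvariants(mol)
  flags <- colinearAtomFlags(mol)
  b <- mol@bonds
  out <- list()
  for (k in seq_len(nrow(b))) {
    if (b$inRing[k]) next
    a1 <- b$a1[k]; a2 <- b$a2[k]
    if (mol@atoms$elem[a1] == "H" || mol@atoms$elem[a2] == "H") next
    nb1 <- heavyNeighbors(mol, a1, exclude = a2)
    nb2 <- heavyNeighbors(mol, a2, exclude = a1)
    if (length(nb1) == 0 || length(nb2) == 0) next  # terminal
    if (flags[a1] || flags[a2]) next                # colinear middle atoms
    r1 <- torsionReferenceAtoms(nb1, inv)
    r2 <- torsionReferenceAtoms(nb2, inv)
    md <- 180
    if (maxDev == "spec") {
      # a symmetric end with m equivalent neighbors caps the attainable
      # deviation: 2 equivalent neighbors -> 90 degrees, 3 -> 60 degrees
      symN <- c(if (length(r1) > 1) length(nb1), if (length(r2) > 1) length(nb2))
      if (length(symN) > 0) md <- if (max(symN) >= 3) 60 else 90
    }
    quartets <- as.matrix(expand.grid(r1, r2))
    quartets <- cbind(quartets[, 1], a1, a2, quartets[, 2])
    out[[length(out) + 1]] <- list(quartets = quartets, maxDev = md,
                                   axis = c(a1, a2), ring = FALSE)
  }
  out
}

# reference atom choice at one end of a torsion: a single least-invariant
# neighbor, or all of them when they are topologically equivalent
torsionReferenceAtoms <- function(nbrs, inv) {
  if (length(nbrs) == 1) return(nbrs)
  iv <- inv[nbrs]
  if (length(unique(iv)) == 1) return(nbrs)          # all equivalent
  if (length(nbrs) == 3) {
    tab <- table(iv)
    if (any(tab == 2)) {
      # two equivalent, one different: the odd one defines the torsion
      odd <- nbrs[iv == as.integer(names(tab)[tab == 1])]
      return(odd)
    }
  }
  nbrs[order(iv, nbrs)][1]
}

# ring torsion definitions: one entry per ring, averaging |dihedral| over
# the ring's consecutive atom quartets
tfdRingTorsions <- function(mol) {
  rings <- ringAtomCycles(mol)
  lapply(rings, function(r) {
    n <- length(r)
    quartets <- t(vapply(seq_len(n), function(i) {
      r[c((i - 2) %% n + 1, (i - 1) %% n + 1, i %% n + 1, (i + 1) %% n + 1)]
    }, integer(4)))
    list(quartets = quartets, maxDev = 180, axis = NA, ring = TRUE)
  })
}

# smallest rings of the heavy-atom graph as ordered atom sequences: for
# every ring bond, the shortest cycle through it (duplicates collapsed) —
# a smallest-set-of-smallest-rings stand-in adequate for torsion extraction
ringAtomCycles <- function(mol) {
  hg <- heavyGraph(mol)
  g <- hg$graph
  el <- igraph::as_edgelist(g)
  ringEdges <- which(!seq_len(nrow(el)) %in%
                       as.integer(igraph::bridges(g)))
  seen <- character(0)
  out <- list()
  for (e in ringEdges) {
    u <- el[e, 1]; v <- el[e, 2]
    g2 <- igraph::delete_edges(g, e)
    sp <- igraph::shortest_paths(g2, from = u, to = v)$vpath[[1]]
    if (length(sp) == 0) next
    cyc <- as.integer(sp)
    key <- paste(sort(cyc), collapse = "-")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1]] <- hg$heavy[cyc]
  }
  out
}

# topological weights: most central bond by minimal std of distance rows,
# beta from w(dmax/2) = 0.1, bond weight exp(-beta d^2)
tfdWeights <- function(mol, torsions) {
  heavy <- which(mol@atoms$elem != "H")
  hg <- heavyGraph(mol)
  dm <- igraph::distances(hg$graph)
  hdeg <- heavyDegree(mol)[heavy]
  nonTerminal <- which(hdeg >= 2)
  if (length(nonTerminal) == 0) return(rep(1, length(torsions)))
  stds <- vapply(nonTerminal, function(i) stats::sd(dm[i, -i]), numeric(1))
  ordIdx <- nonTerminal[order(stds, nonTerminal)]
  aid1 <- ordIdx[1]
  aid2 <- NA_integer_
  for (j in ordIdx[-1]) {
    if (dm[aid1, j] == 1) { aid2 <- j; break }
  }
  if (is.na(aid2)) aid2 <- as.integer(igraph::neighbors(hg$graph, aid1))[1]
  # beta calibrated so that a bond at half the maximal distance weighs 0.1
  hnb <- lapply(seq_along(heavy), function(i)
    as.integer(igraph::neighbors(hg$graph, i)))
  ntBonds <- igraph::as_edgelist(hg$graph)
  keep <- lengths(hnb[ntBonds[, 1]]) > 1 & lengths(hnb[ntBonds[, 2]]) > 1
  ntBonds <- ntBonds[keep, , drop = FALSE]
  dmax <- if (nrow(ntBonds) > 0)
    max(pmax(dm[aid1, ntBonds[, 1]], dm[aid1, ntBonds[, 2]])) else 1
  if (dmax <= 0) dmax <- 1
  beta <- -log(0.1) / (dmax / 2)^2
  invHeavy <- match(seq_len(nrow(mol@atoms)), heavy)
  vapply(torsions, function(tor) {
    if (isTRUE(tor$ring)) {
      q <- tor$quartets
      ringAtoms <- unique(as.vector(q))
      # per ring bond: distance of its closer atom to the central pair, +1
      n <- nrow(q)
      ds <- vapply(seq_len(n), function(i) {
        b1 <- invHeavy[q[i, 2]]; b2 <- invHeavy[q[i, 3]]
        min(dm[aid1, b1], dm[aid1, b2], dm[aid2, b1], dm[aid2, b2]) + 1
      }, numeric(1))
      (n / 2) * exp(-beta * mean(ds)^2)
    } else {
      b1 <- invHeavy[tor$axis[1]]; b2 <- invHeavy[tor$axis[2]]
      d <- if ((b1 == aid1 && b2 == aid2) || (b1 == aid2 && b2 == aid1)) 0
      else min(dm[aid1, b1], dm[aid1, b2], dm[aid2, b1], dm[aid2, b2]) + 1
      exp(-beta * d^2)
    }
  }, numeric(1))
}

tfdTorsionAngles <- function(coords, torsions) {
  lapply(torsions, function(tor) {
    q <- tor$quartets
    angs <- vapply(seq_len(nrow(q)), function(i)
      radToDeg(dihedralAngle(coords[q[i, 1], ], coords[q[i, 2], ],
                             coords[q[i, 3], ], coords[q[i, 4], ])),
      numeric(1))
    if (isTRUE(tor$ring)) mean(abs(angs)) else wrapAngle(degToRad(angs)) * 180 / pi
  })
}

#' Torsion fingerprint deviation between conformers
#'
#' Superposition-free conformer distance in [0, 1]: the torsion angles of
#' non-terminal acyclic bonds and of ring systems are extracted from both
#' conformations, each absolute deviation is normalized by the torsion's
#' maximal possible deviation, weighted by its topological distance from the
#' molecule's most central bond, and averaged. Zero means identical
#' conformations; torsions near the molecular core dominate the score.
#'
#' @param conformer,reference conformers of the same molecule.
#' @param maxDev `"equal"` normalizes every torsion by 180 degrees (the
#'   common default); `"spec"` uses torsion-specific maxima (90/60 degrees
#'   at symmetric ends).
#' @param weighted apply topological weights (default `TRUE`).
#' @return TFD value in [0, 1].
#' @export
conformerTFD <- function(conformer, reference, maxDev = "equal",
                         weighted = TRUE) {
  mol <- conformerMolecule(conformer)
  molB <- conformerMolecule(reference)
  if (!identical(mol@atoms$elem, molB@atoms$elem))
    stop("conformers do not share the same molecule topology", call. = FALSE)
  torsions <- c(tfdTorsionList(mol, maxDev), tfdRingTorsions(mol))
  if (length(torsions) == 0)
    stop(errorCondition(
      paste0("TFD cannot be calculated: '", mol@name,
             "' has no non-terminal acyclic or ring torsions"),
      class = c("torsbo_no_torsions_error", "error")))
  t1 <- tfdTorsionAngles(conformerCoords(conformer), torsions)
  t2 <- tfdTorsionAngles(conformerCoords(reference), torsions)
  devs <- vapply(seq_along(torsions), function(i) {
    diffs <- outer(t1[[i]], t2[[i]], function(a, b) {
      dd <- abs(a - b) %% 360
      pmin(dd, 360 - dd)
    })
    min(diffs) / torsions[[i]]$maxDev
  }, numeric(1))
  w <- if (weighted) tfdWeights(mol, torsions) else rep(1, length(torsions))
  if (sum(w) == 0) return(0)
  min(sum(devs * w) / sum(w), 1)
}
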
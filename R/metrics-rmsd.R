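#' @include torsions.R
NULL

heavyGraph <- function(mol) {
  heavy <- which(mol@atoms$elem != "H")
  idx <- match(seq_len(nrow(mol@atoms)), heavy)
  b <- mol@bonds
  keep <- !is.na(idx[b$a1]) & !is.na(idx[b$a2])
  g <- igraph::graph_from_edgelist(cbind(idx[b$a1[keep]], idx[b$a2[keep]]),
                                   directed = FALSE)
  if (igraph::vcount(g) < length(heavy))
    g <- igraph::add_vertices(g, length(heavy) - igraph::vcount(g))
  igraph::V(g)$color <- as.integer(factor(mol@atoms$elem[heavy]))
  list(graph = g, heavy = heavy)
}

# all heavy-atom automorphisms (element-preserving graph self-isomorphisms),
# as a list of permutations of the heavy-atom indexing
heavyAutomorphisms <- function(mol, max = 10000L) {
  hg <- heavyGraph(mol)
  maps <- igraph::isomorphisms(hg$graph, hg$graph, method = "vf2")
  if (length(maps) > max) {
    warning("automorphism group truncated at ", max, " mappings")
    maps <- maps[seq_len(max)]
  }
  lapply(maps, as.integer)
}

# Kabsch: least-squares RMSD of B onto A over proper rotations
kabschRMSD <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  s <- svd(crossprod(Bc, Ac))
  sgn <- sign(det(tcrossprod(s$v, s$u)))
  dvec <- c(1, 1, sgn)
  Brot <- Bc %*% s$u %*% diag(dvec) %*% t(s$v)
  sqrt(sum((Ac - Brot)^2) / nrow(A))
}

#' Symmetry-aware heavy-atom RMSD between conformers
#'
#' Root-mean-square deviation over heavy atoms, minimized over the
#' molecule's heavy-atom automorphism group (element-preserving graph
#' symmetries), so that e.g. a benzene ring flipped about its twofold axis
#' scores 0. By default each candidate atom mapping is superposed by
#' rigid-body least squares (proper rotations only) before the deviation is
#' computed; `superpose = FALSE` compares coordinates in place.
#'
#' @param conformer,reference [Conformer-class] objects (or
#'   [TorsionMolecule-class], compared at reference coordinates) of the same
#'   molecule topology.
#' @param superpose optimally align before measuring (default `TRUE`).
#' @param symmetry minimize over the automorphism group (default `TRUE`);
#'   `FALSE` uses the identity mapping only.
#' @return RMSD in Angstrom.
#' @export
conformerRMSD <- function(conformer, reference, superpose = TRUE,
                          symmetry = TRUE) {
  cA <- conformerCoords(conformer)
  cB <- conformerCoords(reference)
  molA <- conformerMolecule(conformer)
  molB <- conformerMolecule(reference)
  if (!identical(molA@atoms$elem, molB@atoms$elem) ||
      !identical(molA@bonds[, c("a1", "a2")], molB@bonds[, c("a1", "a2")]))
    stop("conformers do not share the same molecule topology", call. = FALSE)
  heavy <- which(molA@atoms$elem != "H")
  A <- cA[heavy, , drop = FALSE]
  B <- cB[heavy, , drop = FALSE]
  perms <- if (symmetry) heavyAutomorphisms(molA) else
    list(seq_along(heavy))
  vals <- vapply(perms, function(p) {
    Bp <- B[p, , drop = FALSE]
    if (superpose) kabschRMSD(A, Bp) else sqrt(sum((A - Bp)^2) / nrow(A))
  }, numeric(1))
  min(vals)
}

conformerCoords <- function(x) {
  if (is(x, "Conformer")) x@coords
  else if (is(x, "TorsionMolecule")) x@coords
  else stop("expected a Conformer or TorsionMolecule")
}

conformerMolecule <- function(x) {
  if (is(x, "Conformer")) x@molecule else x
}
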
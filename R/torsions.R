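#' @include rotors.R
NULL

# signed dihedral angle (IUPAC convention) of points p1-p2-p3-p4, radians in
# (-pi, pi]; errors on collinear geometry where the angle is undefined
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (sqrt(sum(n1^2)) < 1e-10 * nb2 || sqrt(sum(n2^2)) < 1e-10 * nb2)
    stop("degenerate geometry: three dihedral atoms are collinear",
         call. = FALSE)
  m1 <- cross3(n1, b2 / nb2)
  atan2(sum(m1 * n2), sum(n1 * n2))
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Rodrigues rotation of points (rows of x) about the axis through `origin`
# with unit direction `u` by angle `ang`
rotateAbout <- function(x, origin, u, ang) {
  xc <- sweep(x, 2, origin)
  cosA <- cos(ang); sinA <- sin(ang)
  ux <- xc %*% rbind(c(0, u[3], -u[2]), c(-u[3], 0, u[1]), c(u[2], -u[1], 0))
  uu <- tcrossprod(xc %*% u, u)
  sweep(xc * cosA + ux * sinA + uu * (1 - cosA), 2, origin, `+`)
}

# atoms that move when bond b-c is rotated: the connected component holding c
# after deleting the bond (cached per molecule in an environment would buy
# little; molecules here are small)
movingSets <- function(mol) {
  g <- igraph::graph_from_edgelist(cbind(mol@bonds$a1, mol@bonds$a2),
                                   directed = FALSE)
  if (igraph::vcount(g) < nrow(mol@atoms))
    g <- igraph::add_vertices(g, nrow(mol@atoms) - igraph::vcount(g))
  lapply(seq_len(nrow(mol@rotors)), function(i) {
    b <- mol@rotors$b[i]; cc <- mol@rotors$c[i]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(b, cc)))
    comp <- igraph::components(g2)$membership
    which(comp == comp[cc])
  })
}

#' Drive the rotatable bonds to a torsion vector
#'
#' Produces the conformer whose dihedral angles at the molecule's rotatable
#' bonds equal `theta`, keeping every bond length, bond angle and ring system
#' at its reference value (the fixed-rotor convention). Sterically clashing
#' geometries are returned as-is; dealing with their high energies is the
#' objective's concern.
#'
#' @param mol a [TorsionMolecule-class].
#' @param theta numeric vector of target dihedrals (radians), length
#'   `nRotors(mol)`; any real values are accepted and wrapped.
#' @return a [Conformer-class] with unevaluated energy.
#' @seealso [measureTorsions()]
#' @export
applyTorsions <- function(mol, theta) {
  d <- nrow(mol@rotors)
  if (length(theta) != d)
    stop("torsion vector has length ", length(theta),
         " but the molecule has ", d, " rotatable bonds", call. = FALSE)
  theta <- wrapAngle(theta)
  coords <- mol@coords
  if (d > 0) {
    mov <- movingSets(mol)
    for (i in seq_len(d)) {
      q <- unlist(mol@rotors[i, c("a", "b", "c", "d")])
      cur <- dihedralAngle(coords[q[1], ], coords[q[2], ],
                           coords[q[3], ], coords[q[4], ])
      delta <- wrapToPi(theta[i] - cur)
      # right-hand rotation of the c-side about b->c decreases the IUPAC
      # dihedral, hence the sign
      axis <- coords[q[3], ] - coords[q[2], ]
      u <- axis / sqrt(sum(axis^2))
      coords[mov[[i]], ] <- rotateAbout(coords[mov[[i]], , drop = FALSE],
                                        coords[q[2], ], u, -delta)
    }
  }
  new("Conformer", molecule = mol, coords = coords, torsions = theta,
      energy = NA_real_)
}

#' Measure the dihedral angles at the rotatable bonds
#'
#' @param x a [Conformer-class], or a [TorsionMolecule-class] (measured at
#'   its reference coordinates).
#' @return numeric vector in `[0, 2*pi)`, one angle per rotatable bond.
#' @export
measureTorsions <- function(x) {
  if (is(x, "Conformer")) {
    mol <- x@molecule; coords <- x@coords
  } else if (is(x, "TorsionMolecule")) {
    mol <- x; coords <- x@coords
  } else stop("x must be a Conformer or TorsionMolecule")
  rot <- mol@rotors
  vapply(seq_len(nrow(rot)), function(i) {
    q <- unlist(rot[i, c("a", "b", "c", "d")])
    wrapAngle(dihedralAngle(coords[q[1], ], coords[q[2], ],
                            coords[q[3], ], coords[q[4], ]))
  }, numeric(1))
}
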
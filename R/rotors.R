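#' @include molecule-io.R
NULL

heavyDegree <- function(mol) {
  heavy <- mol@atoms$elem != "H"
  deg <- integer(nrow(mol@atoms))
  for (k in seq_len(nrow(mol@bonds))) {
    a1 <- mol@bonds$a1[k]; a2 <- mol@bonds$a2[k]
    if (heavy[a2]) deg[a1] <- deg[a1] + 1L
    if (heavy[a1]) deg[a2] <- deg[a2] + 1L
  }
  deg
}

heavyNeighbors <- function(mol, atom, exclude = 0L) {
  b <- mol@bonds
  nb <- c(b$a2[b$a1 == atom], b$a1[b$a2 == atom])
  nb <- nb[mol@atoms$elem[nb] != "H" & nb != exclude]
  sort(nb)
}

#' Perceive rotatable bonds
#'
#' A bond is rotatable when it is a single bond, not in a ring, and both of
#' its atoms carry at least two heavy-atom neighbors (non-terminal). This is
#' a purely topological rule: bonds to symmetric tops such as tert-butyl are
#' kept by default, since their rotation still changes atom positions even
#' if the energy is (nearly) invariant; set `excludeSymmetricTops = TRUE` to
#' drop bonds whose off-axis substituents on one side are all identical
#' single-atom leaves (CF3-like rotors).
#'
#' For the axis `b`-`c` (with `b < c`) the dihedral quadruple is chosen
#' deterministically: `a` is the lowest-index heavy neighbor of `b` other
#' than `c`, and `d` the lowest-index heavy neighbor of `c` other than `b`.
#' Rows are sorted by `(b, c)`, so the perception is stable under atom
#' reindexing up to the induced permutation.
#'
#' @param mol a [TorsionMolecule-class].
#' @param excludeSymmetricTops logical; see Details.
#' @return data.frame with columns `a`, `b`, `c`, `d`, `hybPair`,
#'   `periodicity` (`NA` until assigned), `pattern`. Rigid molecules give
#'   zero rows.
#' @examples
#' \dontrun{
#' findRotatableBonds(readMolecule("CCCC", name = "butane"))  # one bond
#' }
#' @export
findRotatableBonds <- function(mol, excludeSymmetricTops = FALSE) {
  b <- mol@bonds
  if (nrow(b) == 0) return(emptyRotorTable())
  hdeg <- heavyDegree(mol)
  heavy <- mol@atoms$elem != "H"
  cand <- which(b$order == 1L & !b$inRing &
                heavy[b$a1] & heavy[b$a2] &
                hdeg[b$a1] >= 2L & hdeg[b$a2] >= 2L)
  rows <- lapply(cand, function(k) {
    bb <- min(b$a1[k], b$a2[k]); cc <- max(b$a1[k], b$a2[k])
    a <- heavyNeighbors(mol, bb, exclude = cc)[1]
    d <- heavyNeighbors(mol, cc, exclude = bb)[1]
    data.frame(a = a, b = bb, c = cc, d = d,
               hybPair = hybPairLabel(mol@atoms$hyb[bb], mol@atoms$hyb[cc]),
               periodicity = NA_integer_, pattern = NA_character_)
  })
  rot <- do.call(rbind, c(rows, list(emptyRotorTable())))
  if (excludeSymmetricTops && nrow(rot) > 0) {
    sym <- vapply(seq_len(nrow(rot)), function(i)
      isSymmetricTop(mol, rot$b[i], rot$c[i]) ||
      isSymmetricTop(mol, rot$c[i], rot$b[i]), logical(1))
    rot <- rot[!sym, , drop = FALSE]
  }
  rot <- rot[order(rot$b, rot$c), , drop = FALSE]
  rownames(rot) <- NULL
  rot
}

# one side of the axis is a symmetric top when its off-axis substituents are
# >= 2 identical single-atom leaves (e.g. CF3, C(CH3)3 at the heavy level)
isSymmetricTop <- function(mol, axisAtom, otherAxisAtom) {
  nb <- heavyNeighbors(mol, otherAxisAtom, exclude = axisAtom)
  if (length(nb) < 2) return(FALSE)
  hdegs <- heavyDegree(mol)[nb]
  elems <- mol@atoms$elem[nb]
  all(hdegs == 1L) && length(unique(elems)) == 1L
}

hybPairLabel <- function(h1, h2) {
  rank <- c(sp = 1, sp2 = 2, sp3 = 3, other = 4)
  hs <- c(h1, h2)[order(rank[c(h1, h2)])]
  paste(hs, collapse = "-")
}

#' Read a SMARTS periodicity library
#'
#' Plain text, one record per line: `SMARTS<TAB>periodicity`. Lines starting
#' with `#` and blank lines are skipped. Records keep file order; the first
#' matching record wins during assignment. A rotatable bond matches a record
#' when some SMARTS hit maps the bond's two axis atoms onto two consecutive
#' pattern atoms, so patterns should be written linearly through the bond
#' (e.g. `O=[CX3][NX3]` for the amide C-N torsion).
#'
#' @param path file path.
#' @return data.frame with columns `smarts` and `periodicity`.
#' @export
readPeriodicityLibrary <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(lines) == 0)
    return(data.frame(smarts = character(0), periodicity = integer(0)))
  parts <- strsplit(lines, "\t")
  bad <- vapply(parts, length, integer(1)) < 2
  if (any(bad))
    stop("malformed periodicity library: line(s) without a tab separator: ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  per <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2)))
  if (any(is.na(per) | per < 1))
    stop("malformed periodicity library: periodicities must be integers >= 1",
         call. = FALSE)
  data.frame(smarts = vapply(parts, `[`, character(1), 1), periodicity = per)
}

#' The bundled torsion periodicity library
#'
#' A small curated subset of common rotatable-bond types (amide, ester,
#' biaryl, conjugated, aryl-alkyl, alkyl-alkyl, amine, ether, thioether).
#' Bonds not covered fall back to hybridization-based defaults.
#'
#' @return data.frame as from [readPeriodicityLibrary()].
#' @export
defaultPeriodicityLibrary <- function() {
  readPeriodicityLibrary(system.file("extdata", "torsion_periodicities.tsv",
                                     package = "torsbo", mustWork = TRUE))
}

#' Assign kernel periodicities to the rotatable bonds
#'
#' Each rotatable bond gets the periodicity of the first library record whose
#' SMARTS matches it (see [readPeriodicityLibrary()] for the matching
#' convention). Unmatched bonds use the hybridization fallback: sp2-sp2 -> 2,
#' sp2-sp3 -> 6, sp3-sp3 -> 3; bonds involving sp or unclassified atoms
#' default to 1 (no torsional structure assumed).
#'
#' @param mol a [TorsionMolecule-class] with perceived rotatable bonds.
#' @param library data.frame with columns `smarts`, `periodicity`, or `NULL`
#'   for fallback-only assignment.
#' @param fallback named integer vector keyed by hybridization pair label.
#' @return the molecule with `rotors$periodicity` and `rotors$pattern`
#'   filled in.
#' @export
assignPeriodicity <- function(mol, library = NULL,
                              fallback = c("sp2-sp2" = 2L, "sp2-sp3" = 6L,
                                           "sp3-sp3" = 3L)) {
  rot <- mol@rotors
  if (nrow(rot) == 0) return(mol)
  if (!is.null(library)) {
    if (!all(c("smarts", "periodicity") %in% names(library)))
      stop("library must have columns 'smarts' and 'periodicity'",
           call. = FALSE)
    if (any(library$periodicity < 1) || any(library$periodicity %% 1 != 0))
      stop("malformed periodicity library: periodicities must be integers >= 1",
           call. = FALSE)
  }
  per <- rep(NA_integer_, nrow(rot))
  pat <- rep(NA_character_, nrow(rot))
  if (!is.null(library) && nrow(library) > 0) {
    obmol <- obmolFromSDFText(moleculeToSDFText(mol))
    for (r in seq_len(nrow(library))) {
      if (all(!is.na(per))) break
      hits <- smartsMatchAtoms(obmol, library$smarts[r])
      if (length(hits) == 0) next
      for (i in which(is.na(per))) {
        axis <- c(rot$b[i], rot$c[i])
        hit <- any(vapply(hits, function(m) {
          if (length(m) < 2) return(FALSE)
          any(vapply(seq_len(length(m) - 1), function(j)
            setequal(m[j:(j + 1)], axis), logical(1)))
        }, logical(1)))
        if (hit) {
          per[i] <- as.integer(library$periodicity[r])
          pat[i] <- library$smarts[r]
        }
      }
    }
  }
  for (i in which(is.na(per))) {
    per[i] <- unname(fallback[rot$hybPair[i]])
    if (is.na(per[i])) per[i] <- 1L
    pat[i] <- "fallback"
  }
  rot$periodicity <- as.integer(per)
  rot$pattern <- pat
  mol@rotors <- rot
  validObject(mol)
  mol
}
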
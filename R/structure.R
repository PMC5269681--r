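# Standard atomic weights (amu), CIAAW conventional values; covers the
# elements found in nucleic acids, proteins, common ions and cofactors.
.atomicWeights <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
  P = 30.973762, S = 32.06, F = 18.998403, CL = 35.45, BR = 79.904,
  I = 126.90447, "NA" = 22.98976928, MG = 24.305, K = 39.0983, CA = 40.078,
  MN = 54.938043, FE = 55.845, CO = 58.933194, NI = 58.6934, CU = 63.546,
  ZN = 65.38, SE = 78.971
)

#' Standard atomic weight of an element
#'
#' @param element Element symbols (case-insensitive).
#' @return Masses in amu.
#' @examples
#' atomicWeight(c("C", "O", "P"))
#' @export
atomicWeight <- function(element) {
  key <- toupper(trimws(element))
  m <- .atomicWeights[key]
  if (anyNA(m))
    stop("unknown element(s): ", paste(unique(key[is.na(m)]), collapse = ", "))
  unname(m)
}

# element symbol from a PDB atom name (columns 13-16), used when the element
# field (columns 77-78) is blank
.elementFromName <- function(name) {
  vapply(name, function(nm) {
    clean <- gsub("[^A-Za-z]", "", nm)
    if (!nzchar(clean))
      stop("cannot infer element from atom name '", nm, "'")
    two <- toupper(substr(clean, 1, 2))
    one <- toupper(substr(clean, 1, 1))
    # single-letter organics take precedence: CA in a nucleotide/protein
    # context is a carbon name, not calcium
    if (one %in% c("H", "C", "N", "O", "P", "S", "F", "K", "I")) one
    else if (two %in% names(.atomicWeights)) two
    else stop("cannot infer element from atom name '", nm, "'")
  }, character(1), USE.NAMES = FALSE)
}

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records into a [MolecularStructure-class]. Fixed-width
#' records are validated first (a malformed record is reported with its line
#' number); the actual parsing is delegated to [bio3d::read.pdb()]. The
#' element is taken from columns 77-78 when present and otherwise inferred
#' from the atom name; masses come from the built-in standard-atomic-weight
#' table.
#'
#' @param x Path to a PDB file, or a character vector of PDB lines.
#' @return A [MolecularStructure-class] (possibly with zero atoms).
#' @examples
#' line <- sprintf("%-6s%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f",
#'                 "ATOM", 1, " C1'", " DT", "A", 1, 1, 2, 3)
#' atoms(readPDBStructure(line))
#' @export
readPDBStructure <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE))
  }
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) {
    empty <- data.frame(name = character(0), resno = integer(0),
                        resname = character(0), chain = character(0),
                        element = character(0), mass = numeric(0),
                        x = numeric(0), y = numeric(0), z = numeric(0),
                        stringsAsFactors = FALSE)
    return(new("MolecularStructure", atoms = empty))
  }
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM/HETATM record at line ", i, ": too short")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      stop("malformed ATOM/HETATM record at line ", i,
           ": non-numeric coordinates")
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE)
  at <- pdb$atom
  element <- trimws(at$elesy)
  blank <- !nzchar(element) | is.na(element)
  if (any(blank)) element[blank] <- .elementFromName(trimws(at$elety[blank]))
  element <- toupper(element)
  atoms <- data.frame(
    name = trimws(at$elety), resno = at$resno, resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "", at$chain), element = element,
    mass = atomicWeight(element),
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  new("MolecularStructure", atoms = atoms)
}

#' Define an atom group for a pseudo-dihedral center
#'
#' @param chain Chain identifiers (recycled against `resno`); "" matches a
#'   blank chain, NA matches any chain.
#' @param resno Residue numbers.
#' @param pattern Regular expression on the atom name (recycled); default
#'   matches every name.
#' @param massWeighted Use the center of mass (TRUE, default) or the
#'   unweighted centroid.
#' @param heavyOnly Exclude hydrogens (default TRUE): the pseudo centers are
#'   built from heavy atoms.
#' @return A [GroupSpec-class].
#' @examples
#' groupSpec(chain = "A", resno = 16:19)
#' @export
groupSpec <- function(chain = NA_character_, resno, pattern = ".*",
                      massWeighted = TRUE, heavyOnly = TRUE) {
  sel <- data.frame(chain = as.character(chain), resno = as.integer(resno),
                    pattern = as.character(pattern),
                    stringsAsFactors = FALSE)
  new("GroupSpec", selectors = sel, massWeighted = massWeighted,
      heavyOnly = heavyOnly)
}

#' Resolve a group against a structure
#'
#' @param structure A [MolecularStructure-class].
#' @param group A [GroupSpec-class].
#' @return Integer indices into `atoms(structure)`.
#' @export
resolveGroup <- function(structure, group) {
  stopifnot(is(structure, "MolecularStructure"), is(group, "GroupSpec"))
  a <- atoms(structure)
  hit <- rep(FALSE, nrow(a))
  sel <- group@selectors
  for (i in seq_len(nrow(sel))) {
    m <- a$resno == sel$resno[i] & grepl(sel$pattern[i], a$name)
    if (!is.na(sel$chain[i])) m <- m & a$chain == sel$chain[i]
    hit <- hit | m
  }
  if (group@heavyOnly) hit <- hit & a$element != "H" & a$element != "D"
  idx <- which(hit)
  if (length(idx) == 0) stop("no atoms matched the group specification")
  idx
}

#' Center of mass of an atom group
#'
#' Mass-weighted mean position of the atoms selected by `group` (unweighted
#' centroid if the group requests it).
#'
#' @param structure A [MolecularStructure-class].
#' @param group A [GroupSpec-class].
#' @return Numeric length-3 position in Angstrom.
#' @export
centerOfMass <- function(structure, group) {
  idx <- resolveGroup(structure, group)
  a <- atoms(structure)[idx, , drop = FALSE]
  w <- if (group@massWeighted) a$mass else rep(1, nrow(a))
  c(sum(w * a$x), sum(w * a$y), sum(w * a$z)) / sum(w)
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Dihedral angle over four points
#'
#' The torsion about the p2-p3 axis, IUPAC sign convention (clockwise
#' rotation of the far bond, viewed from p2 toward p3, is positive), wrapped
#' to (-180, 180]. Near-collinear point triples (cross-product norm below
#' 1e-10 A^2) raise an undefined-dihedral error.
#'
#' @param p1,p2,p3,p4 Numeric length-3 positions (Angstrom).
#' @return Angle in degrees in (-180, 180].
#' @examples
#' pseudoDihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0))   # 0 (cis)
#' pseudoDihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0))  # 180
#' @export
pseudoDihedral <- function(p1, p2, p3, p4) {
  stopifnot(length(p1) == 3, length(p2) == 3, length(p3) == 3,
            length(p4) == 3)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sqrt(sum(b2^2)) < 1e-12)
    stop("undefined dihedral: p2 and p3 coincide")
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("undefined dihedral: collinear points")
  b2n <- b2 / sqrt(sum(b2^2))
  y <- sum(.cross3(n1, n2) * b2n)
  x <- sum(n1 * n2)
  wrapAngle(atan2(y, x) * 180 / pi)
}

#' Assemble the four-center flipping coordinate
#'
#' @param g1,g2,g3,g4 [GroupSpec-class] objects, ordered center 1 to 4.
#' @return A [PseudoDihedralSpec-class].
#' @export
pseudoDihedralSpec <- function(g1, g2, g3, g4) {
  new("PseudoDihedralSpec", groups = list(g1, g2, g3, g4))
}

#' Evaluate the flipping pseudo-dihedral on a structure
#'
#' Computes the four group centers of mass and the dihedral over them. A
#' warning is emitted if any two groups share atoms (the definition tolerates
#' overlap, but it usually indicates a selector mistake).
#'
#' @param structure A [MolecularStructure-class].
#' @param spec A [PseudoDihedralSpec-class].
#' @return Angle in degrees in (-180, 180].
#' @export
evalPseudoDihedral <- function(structure, spec) {
  stopifnot(is(spec, "PseudoDihedralSpec"))
  idx <- lapply(spec@groups, function(g) resolveGroup(structure, g))
  for (i in 1:3) for (j in (i + 1):4) {
    if (length(intersect(idx[[i]], idx[[j]])) > 0) {
      warning("pseudo-dihedral groups ", i, " and ", j, " share atoms")
    }
  }
  ps <- lapply(spec@groups, function(g) centerOfMass(structure, g))
  pseudoDihedral(ps[[1]], ps[[2]], ps[[3]], ps[[4]])
}
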
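# Featurization layouts.
#
# Atom vector (101 = 44 + 11 + 11 + 11 + 11 + 11 + 1 + 1), in order:
#   element symbol one-hot over .ATOM_SYMBOLS + "other" (44),
#   heavy-atom degree one-hot 0..10 (11),
#   total H count one-hot 0..10, clamped (11),
#   implicit H count one-hot 0..10, clamped (11),
#   total valence one-hot 0..10, clamped (11),
#   formal charge one-hot -5..+5, clamped (11),
#   aromatic flag (1), in-ring flag (1).
#
# Substructure vector (35 = 11 + 11 + 11 + 1 + 1), in order:
#   member-atom count one-hot 0..10, clamped (11),
#   neighbouring-substructure count one-hot 0..10, clamped (11),
#   total H count over member atoms one-hot 0..10, clamped (11),
#   contains-ring flag (1), contains-non-ring-bond flag (1).

.ATOM_SYMBOLS <- c(
  "C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na", "Ca", "Fe",
  "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb", "Sn", "Ag", "Pd", "Co",
  "Se", "Ti", "Zn", "H", "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn",
  "Zr", "Cr", "Pt", "Hg", "Pb"
)

# one-hot of a count clamped into 0..(n_slots-1)
.oneHotCount <- function(value, n_slots = 11L) {
  v <- numeric(n_slots)
  v[min(max(value, 0L), n_slots - 1L) + 1L] <- 1
  v
}

.oneHotSymbol <- function(symbol) {
  v <- numeric(length(.ATOM_SYMBOLS) + 1L)
  pos <- match(symbol, .ATOM_SYMBOLS)
  v[if (is.na(pos)) length(v) else pos] <- 1
  v
}

.oneHotCharge <- function(charge) {
  v <- numeric(11L)
  v[min(max(charge, -5L), 5L) + 6L] <- 1
  v
}

#' 101-dimensional one-hot feature vector of one atom
#'
#' Encodes eight kinds of atom information: element symbol, degree, total
#' hydrogen count, implicit hydrogen count, total valence, formal charge,
#' aromaticity and ring membership. Counts above the one-hot range clamp to
#' the last slot. See the package source header of `chem-features.R` for the
#' exact slot layout.
#'
#' @param molecule a [Molecule-class].
#' @param atom_index 1-based atom index.
#' @return numeric binary vector of length 101.
#' @examples
#' sum(atomFeatureVector(parseSmiles("CC"), 1))  # six one-hots + two flags
#' @export
atomFeatureVector <- function(molecule, atom_index) {
  stopifnot(is(molecule, "Molecule"))
  n <- nrow(molecule@atoms)
  if (!(atom_index >= 1 && atom_index <= n))
    stop("atom_index out of range")
  a <- molecule@atoms[atom_index, ]
  c(.oneHotSymbol(a$symbol),
    .oneHotCount(a$degree),
    .oneHotCount(a$total_h),
    .oneHotCount(a$implicit_h),
    .oneHotCount(a$valence),
    .oneHotCharge(a$charge),
    as.numeric(a$aromatic),
    as.numeric(a$in_ring))
}

#' Build the atom-level graph of a molecule
#'
#' Nodes are heavy atoms, `adjacency[i, j] = 1` iff a bond joins atoms i and
#' j (binary, symmetric, zero diagonal; self-loops are added only inside
#' [normalizeAdjacency()]). Feature row i is [atomFeatureVector()] of atom i.
#'
#' @param molecule a [Molecule-class].
#' @return an [AtomGraph-class].
#' @examples
#' adjacency(buildAtomGraph(parseSmiles("CC")))
#' @export
buildAtomGraph <- function(molecule) {
  stopifnot(is(molecule, "Molecule"))
  n <- nrow(molecule@atoms)
  A <- matrix(0, n, n)
  if (nrow(molecule@bonds) > 0) {
    for (r in seq_len(nrow(molecule@bonds))) {
      a <- molecule@bonds[r, "a"]; b <- molecule@bonds[r, "b"]
      A[a, b] <- 1; A[b, a] <- 1
    }
  }
  X <- t(vapply(seq_len(n), function(i) atomFeatureVector(molecule, i),
                numeric(101)))
  new("AtomGraph", adjacency = A, features = X, smiles = molecule@smiles)
}

#' 35-dimensional feature vector of one substructure
#'
#' Encodes five kinds of structural information: member-atom count, number of
#' neighbouring substructures (those sharing at least one atom), total
#' hydrogen count over member atoms, whether the substructure is a ring, and
#' whether it contains a non-ring bond. Counts clamp into 0..10.
#'
#' @param molecule a [Molecule-class].
#' @param sub one substructure from [segmentSubstructures()].
#' @param segmentation the full segmentation the substructure belongs to.
#' @return numeric binary vector of length 35.
#' @export
substructureFeatureVector <- function(molecule, sub, segmentation) {
  stopifnot(is(molecule, "Molecule"))
  n_neigh <- 0L
  for (other in segmentation) {
    if (identical(other$atoms, sub$atoms) && identical(other$kind, sub$kind))
      next
    if (length(intersect(sub$atoms, other$atoms)) > 0) n_neigh <- n_neigh + 1L
  }
  h_total <- sum(molecule@atoms$total_h[sub$atoms])
  c(.oneHotCount(length(sub$atoms)),
    .oneHotCount(n_neigh),
    .oneHotCount(h_total),
    as.numeric(sub$kind == "ring"),
    as.numeric(sub$kind == "bond"))
}

#' Build the substructure-level graph of a molecule
#'
#' Nodes are the substructures in segmentation order; two nodes are adjacent
#' iff their atom sets intersect. Feature row i is
#' [substructureFeatureVector()] of substructure i.
#'
#' @param molecule a [Molecule-class].
#' @param segmentation optional, the output of [segmentSubstructures()];
#'   computed (without fragment keys) when omitted.
#' @return a [SubstructureGraph-class].
#' @examples
#' nNodes(buildSubstructureGraph(parseSmiles("c1ccccc1-c1ccccc1")))  # 3
#' @export
buildSubstructureGraph <- function(molecule, segmentation = NULL) {
  stopifnot(is(molecule, "Molecule"))
  if (is.null(segmentation))
    segmentation <- segmentSubstructures(molecule, keys = FALSE)
  m <- length(segmentation)
  A <- matrix(0, m, m)
  if (m > 1) {
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        if (length(intersect(segmentation[[i]]$atoms,
                             segmentation[[j]]$atoms)) > 0) {
          A[i, j] <- 1; A[j, i] <- 1
        }
      }
    }
  }
  X <- t(vapply(segmentation, function(s)
    substructureFeatureVector(molecule, s, segmentation), numeric(35)))
  if (m == 1) X <- matrix(X, nrow = 1)
  new("SubstructureGraph", adjacency = A, features = X,
      membership = lapply(segmentation, `[[`, "atoms"),
      kinds = vapply(segmentation, `[[`, "", "kind"),
      smiles = molecule@smiles)
}
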
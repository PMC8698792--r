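#' Segment a molecule into substructures
#'
#' A substructure is either (i) a ring cluster: a simple ring, or the fixpoint
#' merge of simple rings that pairwise share at least 3 atoms, or (ii) a pair
#' of atoms joined by a bond that does not belong to any ring. Isolated atoms
#' (including single-atom molecules) yield a degenerate single-atom
#' substructure so that every molecule has a non-empty substructure graph.
#'
#' Each substructure carries a `key`: the canonical SMILES of the extracted
#' fragment (severed attachment valences are hydrogen-filled), used as its
#' identity in a [SubstructureVocabulary-class].
#'
#' @param molecule a [Molecule-class].
#' @param keys logical; compute canonical fragment keys (default TRUE).
#'   Skipping them avoids toolkit round-trips when only the graph topology
#'   is needed.
#' @return list of substructures, each a list with elements `kind`
#'   ("ring", "bond" or "atom"), `atoms` (sorted 1-based indices) and `key`
#'   (canonical fragment SMILES, or NA when `keys = FALSE`). Bond
#'   substructures come first (bond order), then ring clusters, then
#'   degenerate atoms.
#' @examples
#' length(segmentSubstructures(parseSmiles("c1ccccc1-c1ccccc1")))  # 3
#' @export
segmentSubstructures <- function(molecule, keys = TRUE) {
  stopifnot(is(molecule, "Molecule"))
  n <- nrow(molecule@atoms)
  bonds <- molecule@bonds
  rings <- molecule@rings

  subs <- list()

  # non-ring bonds
  ring_edges <- .ringEdgeKeys(rings)
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      a <- bonds[r, "a"]; b <- bonds[r, "b"]
      ek <- paste(min(a, b), max(a, b), sep = "-")
      if (!(ek %in% ring_edges))
        subs[[length(subs) + 1L]] <-
          list(kind = "bond", atoms = sort(unname(c(a, b))),
               key = NA_character_)
    }
  }

  # ring clusters: merge simple rings sharing >= 3 atoms, to a fixpoint
  sets <- lapply(rings, function(cyc) sort(unique(cyc)))
  if (length(sets) > 1) {
    repeat {
      merged <- FALSE
      for (i in seq_along(sets)) {
        if (merged) break
        for (j in seq_along(sets)) {
          if (j <= i) next
          if (length(intersect(sets[[i]], sets[[j]])) >= 3L) {
            sets[[i]] <- sort(union(sets[[i]], sets[[j]]))
            sets[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
      }
      if (!merged) break
    }
  }
  if (length(sets)) {
    set_keys <- vapply(sets, paste, "", collapse = ",")
    sets <- sets[!duplicated(set_keys)]
    for (s in sets)
      subs[[length(subs) + 1L]] <-
        list(kind = "ring", atoms = s, key = NA_character_)
  }

  # isolated atoms (degree 0), incl. single-atom molecules
  covered <- if (length(subs)) unique(unlist(lapply(subs, `[[`, "atoms")))
             else integer(0)
  bonded <- if (nrow(bonds) > 0) unique(c(bonds[, "a"], bonds[, "b"]))
            else integer(0)
  for (a in setdiff(seq_len(n), union(covered, bonded)))
    subs[[length(subs) + 1L]] <-
      list(kind = "atom", atoms = a, key = NA_character_)

  if (keys)
    for (k in seq_along(subs))
      subs[[k]]$key <- .fragmentKey(molecule, subs[[k]]$atoms)
  subs
}

# canonical SMILES of the fragment induced by the given atoms
.fragmentKey <- function(molecule, atom_idx) {
  txt <- .fragmentMolfile(molecule, atom_idx)
  out <- ChemmineOB::convertFormat("SDF", "CAN", txt)
  key <- strsplit(out, "[\t\n]")[[1]][1]
  if (is.na(key) || !nzchar(key))
    stop("failed to derive canonical fragment key for '", molecule@smiles, "'")
  key
}

# V2000 molfile text of the induced fragment (atoms + bonds among them);
# severed valences are left to implicit-hydrogen filling downstream
.fragmentMolfile <- function(molecule, atom_idx) {
  atom_idx <- sort(atom_idx)
  syms <- molecule@atoms$symbol[atom_idx]
  chgs <- molecule@atoms$charge[atom_idx]
  remap <- match(seq_len(nrow(molecule@atoms)), atom_idx)
  b <- molecule@bonds
  keep <- if (nrow(b) > 0)
    which(b[, "a"] %in% atom_idx & b[, "b"] %in% atom_idx) else integer(0)
  header <- c("", "  fragment", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                      length(atom_idx), length(keep)))
  atom_lines <- sprintf(
    "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    syms)
  bond_lines <- vapply(keep, function(r) sprintf(
    "%3d%3d%3d  0  0  0  0", remap[b[r, "a"]], remap[b[r, "b"]],
    b[r, "order"]), "")
  chg_lines <- character(0)
  charged <- which(chgs != 0L)
  if (length(charged))
    chg_lines <- sprintf("M  CHG%3d%s", length(charged),
                         paste(sprintf("%4d%4d", charged, chgs[charged]),
                               collapse = ""))
  paste(c(header, atom_lines, bond_lines, chg_lines, "M  END", "$$$$"),
        collapse = "\n")
}

#' Build a substructure vocabulary from SMILES strings
#'
#' Parses and segments every molecule and collects the canonical fragment
#' keys in first-seen order. Idempotent under repeated input: rebuilding from
#' the same SMILES list yields an identical vocabulary.
#'
#' @param smiles_list character vector of SMILES.
#' @return a [SubstructureVocabulary-class].
#' @examples
#' buildVocabulary(c("CC", "c1ccccc1-c1ccccc1"))
#' @export
buildVocabulary <- function(smiles_list) {
  stopifnot(is.character(smiles_list), length(smiles_list) > 0)
  keys <- character(0)
  for (smi in smiles_list) {
    mol <- parseSmiles(smi)
    subs <- segmentSubstructures(mol)
    for (s in subs)
      if (!(s$key %in% keys)) keys <- c(keys, s$key)
  }
  new("SubstructureVocabulary", keys = keys)
}

#' Write a substructure vocabulary as TSV
#'
#' One line per entry: 0-based id, TAB, canonical fragment SMILES. The file
#' is byte-identical across rebuilds from the same input.
#'
#' @param vocab a [SubstructureVocabulary-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeVocabulary <- function(vocab, path) {
  stopifnot(is(vocab, "SubstructureVocabulary"))
  lines <- sprintf("%d\t%s", seq_along(vocab@keys) - 1L, vocab@keys)
  writeLines(lines, path)
  invisible(path)
}

#' Read a substructure vocabulary from TSV
#'
#' @param path TSV file written by [writeVocabulary()].
#' @return a [SubstructureVocabulary-class].
#' @export
readVocabulary <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = c("integer", "character"))
  if (!identical(tab[[1]], seq_len(nrow(tab)) - 1L))
    stop("vocabulary ids must be 0-based and contiguous")
  new("SubstructureVocabulary", keys = tab[[2]])
}
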
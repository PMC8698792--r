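#' Parse a SMILES string into a Molecule
#'
#' Parses with the OpenBabel toolkit (via ChemmineR/ChemmineOB): aromaticity
#' is perceived and implicit hydrogens are assigned by the toolkit's standard
#' sanitization. Explicit hydrogen atoms in the input are folded into the
#' per-atom hydrogen counts, so the returned graph contains heavy atoms only,
#' in the toolkit's parse order (1-based indices).
#'
#' @param smiles a single non-empty SMILES string.
#' @return a [Molecule-class] object.
#' @examples
#' mol <- parseSmiles("CC")
#' nNodes(mol)
#' @export
parseSmiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles))
    stop("'smiles' must be a single non-empty string")

  # hydrogen-added structure: hydrogens are appended after the original
  # atoms, so heavy-atom order is the toolkit's parse order
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", smiles,
                              options = data.frame(names = "h", args = "")),
    error = function(e)
      stop(sprintf("failed to parse SMILES '%s': %s", smiles,
                   conditionMessage(e)), call. = FALSE))
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  counts <- .molfileCounts(lines)
  if (is.null(counts) || counts[1] < 1L)
    stop(sprintf("failed to parse SMILES '%s': no atoms", smiles),
         call. = FALSE)
  if (counts[2] == 0L) return(.bareAtomMolecule(smiles, lines))

  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  sdfh <- suppressWarnings(ChemmineR::read.SDFset(tmp))[[1]]
  ab <- ChemmineR::atomblock(sdfh)
  symbols <- sub("_.*$", "", rownames(ab))
  charges <- .chargesFromAtomblock(ab)
  bond_all <- .bondRows(ChemmineR::bondblock(sdfh))

  heavy <- which(symbols != "H")
  if (length(heavy) == 0L)
    stop(sprintf("failed to parse SMILES '%s': no heavy atoms", smiles),
         call. = FALSE)
  if (!identical(heavy, seq_along(heavy)))
    stop("internal error: hydrogens were not appended after heavy atoms")
  n <- length(heavy)

  total_h <- integer(n)
  keep <- logical(nrow(bond_all))
  for (r in seq_len(nrow(bond_all))) {
    a <- bond_all[r, 1]; b <- bond_all[r, 2]
    ha <- symbols[a] == "H"; hb <- symbols[b] == "H"
    if (ha && !hb) total_h[b] <- total_h[b] + 1L
    if (hb && !ha) total_h[a] <- total_h[a] + 1L
    keep[r] <- !ha && !hb
  }
  bonds <- bond_all[keep, , drop = FALSE]
  colnames(bonds) <- c("a", "b", "order")
  storage.mode(bonds) <- "integer"

  explicit_h <- .explicitHydrogens(smiles, n)
  implicit_h <- pmax(total_h - explicit_h, 0L)

  degree <- integer(n)
  bond_order_sum <- numeric(n)
  for (r in seq_len(nrow(bonds))) {
    a <- bonds[r, "a"]; b <- bonds[r, "b"]; o <- bonds[r, "order"]
    degree[a] <- degree[a] + 1L
    degree[b] <- degree[b] + 1L
    bond_order_sum[a] <- bond_order_sum[a] + o
    bond_order_sum[b] <- bond_order_sum[b] + o
  }
  valence <- as.integer(round(bond_order_sum)) + total_h

  rings <- .ringsFromBonds(n, bonds)
  in_ring <- logical(n)
  if (length(rings)) in_ring[unique(unlist(rings))] <- TRUE
  aromatic <- .aromaticAtoms(sdfh, n)

  atoms <- data.frame(
    symbol = symbols[heavy], charge = charges[heavy],
    aromatic = aromatic, in_ring = in_ring, degree = degree,
    total_h = total_h, implicit_h = implicit_h, valence = valence,
    stringsAsFactors = FALSE
  )
  new("Molecule", atoms = atoms, bonds = bonds, rings = rings,
      smiles = smiles, sdf = sdfh)
}

# counts line (atoms, bonds) of a V2000 molfile, or NULL
.molfileCounts <- function(lines) {
  if (length(lines) < 4L) return(NULL)
  cl <- lines[4]
  na <- suppressWarnings(as.integer(substr(cl, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(cl, 4, 6)))
  if (is.na(na) || is.na(nb)) NULL else c(na, nb)
}

# a molecule that is one atom with no hydrogens (e.g. a bare halide or metal
# ion): the toolkit's SDF reader cannot represent bond-free records, so the
# single atom line is read off the molfile text directly
.bareAtomMolecule <- function(smiles, lines) {
  al <- lines[5]
  symbol <- trimws(substr(al, 32, 34))
  code <- suppressWarnings(as.integer(substr(al, 37, 39)))
  chg <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L,
           `6` = -2L, `7` = -3L)[as.character(code)]
  if (is.na(chg)) chg <- 0L
  mchg <- grep("^M  CHG", lines, value = TRUE)
  if (length(mchg) == 1L) {
    fields <- as.integer(strsplit(trimws(sub("^M  CHG *[0-9]+", "", mchg[1])),
                                  " +")[[1]])
    if (length(fields) >= 2L) chg <- fields[2]
  }
  if (!nzchar(symbol) || symbol == "H")
    stop(sprintf("failed to parse SMILES '%s': no heavy atoms", smiles),
         call. = FALSE)
  atoms <- data.frame(symbol = symbol, charge = chg, aromatic = FALSE,
                      in_ring = FALSE, degree = 0L, total_h = 0L,
                      implicit_h = 0L, valence = 0L, stringsAsFactors = FALSE)
  bonds <- matrix(integer(0), ncol = 3,
                  dimnames = list(NULL, c("a", "b", "order")))
  new("Molecule", atoms = atoms, bonds = bonds, rings = list(),
      smiles = smiles, sdf = NULL)
}

# Bond rows (a, b, order) from a bondblock; bond-free molecules come back
# from the toolkit as NULL, zero rows or a zero-padded 2-column stub.
.bondRows <- function(bb) {
  empty <- matrix(integer(0), ncol = 3)
  if (is.null(bb) || nrow(bb) == 0L || ncol(bb) < 3L) return(empty)
  m <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
  m <- m[m[, 1] > 0L & m[, 2] > 0L, , drop = FALSE]
  if (nrow(m) == 0L) empty else m
}

# Formal charges from the molfile atom-line charge code
# (0 none, 1 = +3, 2 = +2, 3 = +1, 4 = radical, 5 = -1, 6 = -2, 7 = -3).
.chargesFromAtomblock <- function(ab) {
  code <- if ("C6" %in% colnames(ab)) as.integer(ab[, "C6"])
          else integer(nrow(ab))
  map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
           `5` = -1L, `6` = -2L, `7` = -3L)
  chg <- map[as.character(code)]
  chg[is.na(chg)] <- 0L
  unname(chg)
}

# Hydrogen atoms written explicitly in the SMILES, per heavy atom, from the
# plain (no hydrogen addition) parse. A plain parse without bonds can only
# be a single heavy atom, which has no explicit hydrogens.
.explicitHydrogens <- function(smiles, n_heavy) {
  expl <- integer(n_heavy)
  if (!grepl("H", smiles, fixed = TRUE)) return(expl)
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles))[[1]],
                  error = function(e) NULL)
  if (is.null(sdf)) return(expl)
  ab <- tryCatch(ChemmineR::atomblock(sdf), error = function(e) NULL)
  if (is.null(ab)) return(expl)
  symbols <- sub("_.*$", "", rownames(ab))
  heavy <- which(symbols != "H")
  if (length(heavy) != n_heavy) return(expl)
  map <- rep(NA_integer_, length(symbols))
  map[heavy] <- seq_len(n_heavy)
  bb <- .bondRows(ChemmineR::bondblock(sdf))
  for (r in seq_len(nrow(bb))) {
    a <- bb[r, 1]; b <- bb[r, 2]
    if (symbols[a] == "H" && symbols[b] != "H")
      expl[map[b]] <- expl[map[b]] + 1L
    if (symbols[b] == "H" && symbols[a] != "H")
      expl[map[a]] <- expl[map[a]] + 1L
  }
  expl
}

# Aromatic flags from the toolkit's aromatic-ring perception (hydrogen
# atoms cannot be ring members, so the hydrogen-added structure gives the
# same rings with identical heavy-atom numbering).
.aromaticAtoms <- function(sdf, n_atoms) {
  aromatic <- logical(n_atoms)
  if (is.null(sdf)) return(aromatic)
  bb <- .bondRows(ChemmineR::bondblock(sdf))
  if (nrow(bb) < 3) return(aromatic)   # no ring possible
  res <- tryCatch(
    ChemmineR::rings(sdf, type = "all", arom = TRUE),
    error = function(e) NULL
  )
  if (is.null(res)) return(aromatic)
  ringlist <- res$RINGS
  flags <- res$AROMATIC
  if (length(ringlist) == 0) return(aromatic)
  for (k in seq_along(ringlist)) {
    if (isTRUE(flags[[k]])) {
      idx <- as.integer(sub("^.*_", "", ringlist[[k]]))
      idx <- idx[idx <= n_atoms]
      aromatic[idx] <- TRUE
    }
  }
  aromatic
}
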
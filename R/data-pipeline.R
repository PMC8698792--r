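# Dataset I/O, the Kd -> pKd transform, the 6-part split with 5-fold CV
# assignment, and the synthetic benchmark generator.

#' Transform a dissociation constant to pKd
#'
#' `pKd = -log10(Kd / 1e9)` with Kd in nanomolar: 1 nM binds at pKd 9,
#' 1e9 nM (1 M) at pKd 0. Strictly decreasing in Kd.
#'
#' @param kd_nM dissociation constant in nM, strictly positive.
#' @return pKd value(s).
#' @examples
#' kdToPkd(c(1e9, 1e4, 1))  # 0 5 9
#' @export
kdToPkd <- function(kd_nM) {
  stopifnot(is.numeric(kd_nM))
  if (any(!is.finite(kd_nM)) || any(kd_nM <= 0))
    stop("Kd must be finite and strictly positive")
  -log10(kd_nM / 1e9)
}

.checkRecords <- function(df, path = NULL) {
  need <- c("drug_id", "smiles", "protein_id", "sequence", "affinity")
  if (!all(need %in% names(df)))
    stop("dataset must have columns ", paste(need, collapse = ", "))
  bad <- which(!is.finite(df$affinity) | !nzchar(df$smiles) |
                 !nzchar(df$sequence))
  if (length(bad))
    stop(sprintf("malformed record%s at line%s %s%s",
                 if (length(bad) > 1) "s" else "",
                 if (length(bad) > 1) "s" else "",
                 paste(bad + 1L, collapse = ", "),
                 if (is.null(path)) "" else paste0(" of ", path)))
  df
}

#' Load an affinity dataset
#'
#' Two layouts are supported. `triples_csv`: a CSV with columns `drug_id`,
#' `smiles`, `protein_id`, `sequence`, `affinity`, one record per row.
#' `matrix_style`: a directory containing `compounds.txt` (id TAB smiles),
#' `proteins.txt` (id TAB sequence) and `affinities.tsv` (dense
#' compounds x proteins matrix, `NA` for missing pairs); records are emitted
#' in row-major order, skipping the missing-value sentinel. With
#' `transform = "pkd"`, raw Kd values in nM are converted by [kdToPkd()]
#' (KIBA-style scores pass through with the default `"none"`).
#'
#' @param path CSV file or matrix-style directory.
#' @param format "triples_csv" or "matrix_style".
#' @param transform "none" or "pkd".
#' @return data.frame of affinity records.
#' @export
loadDataset <- function(path, format = c("triples_csv", "matrix_style"),
                        transform = c("none", "pkd")) {
  format <- match.arg(format)
  transform <- match.arg(transform)
  if (format == "triples_csv") {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    df <- .checkRecords(df, path)
  } else {
    files <- file.path(path, c("compounds.txt", "proteins.txt",
                               "affinities.tsv"))
    if (!all(file.exists(files)))
      stop("matrix-style dataset needs compounds.txt, proteins.txt and ",
           "affinities.tsv under ", path)
    comp <- utils::read.delim(files[1], header = FALSE,
                              col.names = c("id", "smiles"),
                              stringsAsFactors = FALSE)
    prot <- utils::read.delim(files[2], header = FALSE,
                              col.names = c("id", "sequence"),
                              stringsAsFactors = FALSE)
    aff <- as.matrix(utils::read.delim(files[3], header = FALSE,
                                       na.strings = "NA"))
    if (nrow(aff) != nrow(comp) || ncol(aff) != nrow(prot))
      stop("affinity matrix shape does not match compound/protein lists")
    keep <- which(!is.na(t(aff)))          # row-major order
    ij <- arrayInd(keep, c(nrow(prot), nrow(comp)))
    df <- data.frame(drug_id = comp$id[ij[, 2]],
                     smiles = comp$smiles[ij[, 2]],
                     protein_id = prot$id[ij[, 1]],
                     sequence = prot$sequence[ij[, 1]],
                     affinity = t(aff)[keep],
                     stringsAsFactors = FALSE)
    df <- .checkRecords(df)
  }
  for (i in seq_len(nrow(df)))
    tryCatch(parseSmiles(df$smiles[i]), error = function(e)
      stop(sprintf("compound '%s': unparseable SMILES '%s'",
                   df$drug_id[i], df$smiles[i]), call. = FALSE))
  if (transform == "pkd") df$affinity <- kdToPkd(df$affinity)
  df
}

#' Write affinity records as a triples CSV
#'
#' @param records data.frame of affinity records.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeTriplesCsv <- function(records, path) {
  .checkRecords(records)
  utils::write.csv(
    records[, c("drug_id", "smiles", "protein_id", "sequence", "affinity")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a dataset into six parts with cross-validation folds
#'
#' Seeded shuffle into six near-equal parts (sizes differ by at most one);
#' part 1 is the held-out test part, parts 2..6 are the five training folds.
#'
#' @param n_records number of records (>= 6), or a data.frame of records.
#' @param seed RNG seed.
#' @return list with `parts` (list of six index vectors), `test`
#'   (= `parts[[1]]`) and `folds` (parts 2..6, named fold1..fold5).
#' @export
splitDataset <- function(n_records, seed = 1) {
  if (is.data.frame(n_records)) n_records <- nrow(n_records)
  stopifnot(is.numeric(n_records), n_records >= 6)
  n <- as.integer(n_records)
  set.seed(seed)
  ord <- sample.int(n)
  part_of <- rep(seq_len(6L), length.out = n)   # sizes differ by <= 1
  parts <- lapply(seq_len(6L), function(k) sort(ord[part_of == k]))
  list(parts = parts, test = parts[[1]],
       folds = stats::setNames(parts[2:6], paste0("fold", 1:5)))
}

# ---- synthetic benchmark ----

# fragment grammar: closed SMILES pieces that stay valid under concatenation
.SYN_RINGS <- data.frame(
  smiles = c("c1ccccc1", "c1ccncc1", "c1ccsc1", "C1CCCCC1", "C1CCNCC1",
             "C1CCOC1"),
  heavy = c(6L, 6L, 5L, 6L, 6L, 5L),
  stringsAsFactors = FALSE)
.SYN_CHAINS <- data.frame(
  smiles = c("C", "CC", "CCC", "CO", "CN", "CCO", "C(C)C"),
  heavy = c(1L, 2L, 3L, 2L, 2L, 3L, 3L),
  stringsAsFactors = FALSE)
.SYN_HALOGENS <- data.frame(
  smiles = c("F", "Cl", "Br"), heavy = c(1L, 1L, 1L),
  stringsAsFactors = FALSE)

# hydrophobic amino acids used by the toy affinity function
.HYDROPHOBIC <- c("A", "C", "F", "I", "L", "M", "V", "W")

# toy affinity coefficients: intercept, aromatic rings, heavy atoms / 10,
# hydrophobic residue fraction -- chosen to span a pKd-like 4..10 range
.SYN_COEF <- c(a = 4, b = 0.6, c = 0.8, d = 2)

#' Number of aromatic rings of a molecule
#'
#' Simple rings in which every atom is aromatic.
#'
#' @param molecule a [Molecule-class].
#' @return integer count.
#' @export
countAromaticRings <- function(molecule) {
  stopifnot(is(molecule, "Molecule"))
  sum(vapply(molecule@rings, function(r)
    all(molecule@atoms$aromatic[r]), logical(1)))
}

#' Number of heavy atoms of a molecule
#' @param molecule a [Molecule-class].
#' @return integer count.
#' @export
countHeavyAtoms <- function(molecule) {
  stopifnot(is(molecule, "Molecule"))
  nrow(molecule@atoms)
}

#' Fraction of hydrophobic residues in a protein sequence
#'
#' Hydrophobic set: A, C, F, I, L, M, V, W.
#'
#' @param sequence amino-acid sequence.
#' @return fraction in `[0, 1]`.
#' @export
hydrophobicFraction <- function(sequence) {
  letters <- strsplit(toupper(sequence), "")[[1]]
  mean(letters %in% .HYDROPHOBIC)
}

#' Toy affinity of a drug-protein pair
#'
#' The smooth descriptor function the synthetic benchmark labels with:
#' `4 + 0.6 * aromatic rings + 0.8 * heavy atoms / 10 +
#' 2 * hydrophobic fraction`, spanning a pKd-like range.
#'
#' @param molecule a [Molecule-class] (or SMILES string).
#' @param sequence protein sequence.
#' @return scalar noise-free affinity.
#' @export
syntheticAffinity <- function(molecule, sequence) {
  if (is.character(molecule)) molecule <- parseSmiles(molecule)
  unname(.SYN_COEF["a"] + .SYN_COEF["b"] * countAromaticRings(molecule) +
    .SYN_COEF["c"] * countHeavyAtoms(molecule) / 10 +
    .SYN_COEF["d"] * hydrophobicFraction(sequence))
}

# one random SMILES from the fragment grammar, <= 40 heavy atoms by
# construction (max 1 + 3 blocks * 6 + 1 = 20)
.randomSmiles <- function() {
  pieces <- .SYN_CHAINS$smiles[sample.int(nrow(.SYN_CHAINS), 1)]
  for (k in seq_len(sample(1:3, 1))) {
    pool <- if (stats::runif(1) < 0.6) .SYN_RINGS else .SYN_CHAINS
    pieces <- c(pieces, pool$smiles[sample.int(nrow(pool), 1)])
  }
  if (stats::runif(1) < 0.3)
    pieces <- c(pieces, .SYN_HALOGENS$smiles[sample.int(3, 1)])
  paste(pieces, collapse = "")
}

.randomProtein <- function(min_len = 50, max_len = 300) {
  n <- sample(min_len:max_len, 1)
  paste(sample(setdiff(.AA_TOKENS, "X"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic affinity dataset
#'
#' Drugs are assembled from a fixed fragment grammar (aromatic and aliphatic
#' rings, short chains, optional terminal halogen), guaranteeing parseable
#' SMILES with at most 40 heavy atoms. Proteins are uniform random sequences
#' over the 20 standard residues with lengths 50-300. The label is the
#' smooth descriptor function [syntheticAffinity()] plus Gaussian noise.
#' Fully reproducible for a fixed seed.
#'
#' @param n_drugs number of distinct drugs.
#' @param n_proteins number of distinct proteins.
#' @param n_records number of (drug, protein) pairs, at most
#'   `n_drugs * n_proteins` (pairs are sampled without replacement).
#' @param noise_sd standard deviation of the Gaussian label noise.
#' @param seed RNG seed.
#' @return data.frame of affinity records.
#' @export
generateSyntheticDataset <- function(n_drugs = 50, n_proteins = 20,
                                     n_records = 500, noise_sd = 0.2,
                                     seed = 1) {
  stopifnot(n_drugs >= 1, n_proteins >= 1, n_records >= 1, noise_sd >= 0)
  if (n_records > n_drugs * n_proteins)
    stop("n_records exceeds the number of distinct drug-protein pairs")
  set.seed(seed)
  drugs <- character(0)
  while (length(drugs) < n_drugs)
    drugs <- unique(c(drugs, .randomSmiles()))
  drugs <- drugs[seq_len(n_drugs)]
  prots <- vapply(seq_len(n_proteins), function(i) .randomProtein(), "")

  base_drug <- vapply(drugs, function(s) syntheticAffinity(s, "A") -
                        .SYN_COEF["d"] * 1, numeric(1))   # protein part off
  base_prot <- .SYN_COEF["d"] *
    vapply(prots, hydrophobicFraction, numeric(1))

  pair_idx <- sample.int(n_drugs * n_proteins, n_records)
  di <- ((pair_idx - 1L) %% n_drugs) + 1L
  pi_ <- ((pair_idx - 1L) %/% n_drugs) + 1L
  affinity <- base_drug[di] + base_prot[pi_] +
    if (noise_sd > 0) stats::rnorm(n_records, 0, noise_sd) else 0
  data.frame(drug_id = sprintf("D%03d", di), smiles = drugs[di],
             protein_id = sprintf("P%03d", pi_), sequence = prots[pi_],
             affinity = unname(affinity), stringsAsFactors = FALSE)
}
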
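test_that("SMILES parsing perceives atoms, bonds, rings and aromaticity", {
  eth <- parseSmiles("CC")
  expect_equal(nNodes(eth), 2)
  expect_equal(nrow(bondTable(eth)), 1)
  expect_length(findSimpleRings(eth), 0)
  expect_false(any(atomTable(eth)$aromatic))

  benz <- parseSmiles("c1ccccc1")
  expect_equal(nNodes(benz), 6)
  expect_equal(nrow(bondTable(benz)), 6)
  expect_true(all(atomTable(benz)$aromatic))
  expect_true(all(atomTable(benz)$in_ring))
  expect_length(findSimpleRings(benz), 1)
  expect_setequal(findSimpleRings(benz)[[1]], 1:6)

  expect_error(parseSmiles("notasmiles("), "notasmiles")
  expect_error(parseSmiles(""), "non-empty")
})

test_that("naphthalene has two six-atom rings sharing exactly two atoms", {
  rings <- findSimpleRings(parseSmiles("c1ccc2ccccc2c1"))
  expect_length(rings, 2)
  expect_equal(sort(lengths(rings)), c(6, 6))
  expect_length(intersect(rings[[1]], rings[[2]]), 2)
})

test_that("atom feature vectors follow the documented 101-slot layout", {
  eth <- parseSmiles("CC")
  v <- atomFeatureVector(eth, 1)
  expect_length(v, 101)
  expect_true(all(v %in% c(0, 1)))
  # groups: symbol 1:44, degree 45:55, totalH 56:66, implicitH 67:77,
  # valence 78:88, charge 89:99, aromatic 100, ring 101
  expect_equal(which(v[1:44] == 1), 1)          # carbon is the first symbol
  expect_equal(which(v[45:55] == 1) - 1, 1)     # degree 1
  expect_equal(which(v[56:66] == 1) - 1, 3)     # three hydrogens
  expect_equal(which(v[78:88] == 1) - 1, 4)     # valence 4
  expect_equal(v[100], 0)
  expect_equal(v[101], 0)

  anion <- parseSmiles("[O-]C")
  w <- atomFeatureVector(anion, 1)
  expect_equal(which(w[89:99] == 1) - 6, -1)    # formal charge -1

  arom <- atomFeatureVector(parseSmiles("c1ccccc1"), 1)
  expect_equal(arom[100], 1)
  expect_equal(arom[101], 1)
})

test_that("feature row sums obey the one-hot group structure", {
  for (smi in oracle_molecules) {
    mol <- parseSmiles(smi)
    X <- nodeFeatures(buildAtomGraph(mol))
    expect_equal(ncol(X), 101)
    expect_true(all(rowSums(X) %in% 6:8), info = smi)
    S <- nodeFeatures(buildSubstructureGraph(mol))
    expect_equal(ncol(S), 35)
    expect_true(all(rowSums(S) %in% 3:5), info = smi)
  }
})

test_that("atom graphs mirror the bond structure", {
  expect_equal(adjacency(buildAtomGraph(parseSmiles("CC"))),
               matrix(c(0, 1, 1, 0), 2))
  expect_equal(adjacency(buildAtomGraph(parseSmiles("C"))),
               matrix(0, 1, 1))
  benz <- buildAtomGraph(parseSmiles("c1ccccc1"))
  expect_equal(unname(rowSums(adjacency(benz))), rep(2, 6))
  expect_true(validObject(benz))
})

test_that("segmentation matches hand counts on the reference molecules", {
  counts <- c("CC" = 1, "c1ccccc1" = 1, "c1ccccc1-c1ccccc1" = 3,
              "c1ccc2ccccc2c1" = 2, "C1CC2CCC1C2" = 1)
  for (smi in names(counts))
    expect_length(segmentSubstructures(parseSmiles(smi), keys = FALSE),
                  unname(counts[smi]))

  bi <- segmentSubstructures(parseSmiles("c1ccccc1-c1ccccc1"), keys = FALSE)
  expect_setequal(vapply(bi, `[[`, "", "kind"), c("bond", "ring", "ring"))

  # norbornane: two 5-rings share 3 atoms and merge into one 7-atom cluster
  nor <- segmentSubstructures(parseSmiles("C1CC2CCC1C2"), keys = FALSE)
  expect_equal(nor[[1]]$kind, "ring")
  expect_length(nor[[1]]$atoms, 7)

  # single atom: one degenerate substructure
  single <- segmentSubstructures(parseSmiles("C"))
  expect_length(single, 1)
  expect_equal(single[[1]]$kind, "atom")
})

test_that("segmentation equals the brute-force oracle on small molecules", {
  for (smi in oracle_molecules) {
    mol <- parseSmiles(smi)
    expect_lte(nNodes(mol), 8)
    got <- segmentation_signature(segmentSubstructures(mol, keys = FALSE))
    want <- segmentation_signature(oracle_segmentation(mol))
    expect_equal(got, want, info = smi)
  }
})

test_that("every atom is covered and every bond classified exactly once", {
  set.seed(42)
  corpus <- generateSyntheticDataset(n_drugs = 25, n_proteins = 1,
                                     n_records = 25, noise_sd = 0,
                                     seed = 42)$smiles
  for (smi in unique(corpus)) {
    mol <- parseSmiles(smi)
    subs <- segmentSubstructures(mol, keys = FALSE)
    expect_setequal(unique(unlist(lapply(subs, `[[`, "atoms"))),
                    seq_len(nNodes(mol)))
    # each bond: inside >= 1 ring substructure XOR is a bond substructure
    ring_sets <- lapply(Filter(function(s) s$kind == "ring", subs),
                        `[[`, "atoms")
    bond_sets <- lapply(Filter(function(s) s$kind == "bond", subs),
                        `[[`, "atoms")
    b <- bondTable(mol)
    for (r in seq_len(nrow(b))) {
      pair <- sort(unname(b[r, 1:2]))
      in_ring <- any(vapply(ring_sets, function(s)
        all(pair %in% s), logical(1)))
      is_bond_sub <- any(vapply(bond_sets, function(s)
        identical(s, pair), logical(1)))
      expect_true(xor(in_ring, is_bond_sub), info = paste(smi, r))
    }
    # merge fixpoint: no two ring substructures share >= 3 atoms
    if (length(ring_sets) > 1)
      for (i in seq_along(ring_sets))
        for (j in seq_along(ring_sets))
          if (i < j)
            expect_lt(length(intersect(ring_sets[[i]], ring_sets[[j]])), 3)
  }
})

test_that("vocabulary deduplicates, keeps first-seen order and round-trips", {
  expect_length(vocabularyKeys(buildVocabulary("CC")), 1)
  expect_length(vocabularyKeys(buildVocabulary(c("CC", "CC"))), 1)
  expect_length(vocabularyKeys(buildVocabulary("c1ccccc1-c1ccccc1")), 2)

  smi <- c("CCO", "c1ccccc1-c1ccccc1", "C1CC1C")
  v1 <- buildVocabulary(smi)
  v2 <- buildVocabulary(c(smi, smi))     # idempotent under repetition
  expect_identical(vocabularyKeys(v1), vocabularyKeys(v2))

  f1 <- tempfile(); f2 <- tempfile()
  writeVocabulary(v1, f1)
  writeVocabulary(buildVocabulary(smi), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))   # byte-identical
  expect_identical(vocabularyKeys(readVocabulary(f1)), vocabularyKeys(v1))
  expect_error(buildVocabulary(c("CC", "notasmiles(")), "notasmiles")
})

test_that("substructure features and graph match hand-derived values", {
  eth <- parseSmiles("CC")
  seg <- segmentSubstructures(eth, keys = FALSE)
  v <- substructureFeatureVector(eth, seg[[1]], seg)
  expect_length(v, 35)
  expect_equal(which(v[1:11] == 1) - 1, 2)    # two atoms
  expect_equal(which(v[12:22] == 1) - 1, 0)   # no neighbours
  expect_equal(which(v[23:33] == 1) - 1, 6)   # six hydrogens
  expect_equal(v[34], 0)                      # not a ring
  expect_equal(v[35], 1)                      # a non-ring bond

  benz <- parseSmiles("c1ccccc1")
  segb <- segmentSubstructures(benz, keys = FALSE)
  w <- substructureFeatureVector(benz, segb[[1]], segb)
  expect_equal(which(w[1:11] == 1) - 1, 6)
  expect_equal(which(w[12:22] == 1) - 1, 0)
  expect_equal(w[34], 1)
  expect_equal(w[35], 0)

  g <- buildSubstructureGraph(parseSmiles("c1ccccc1-c1ccccc1"))
  expect_equal(nNodes(g), 3)
  # path topology ring - bond - ring: the bond node has degree 2
  expect_setequal(rowSums(adjacency(g)), c(1, 2, 1))
  expect_true(validObject(g))
  expect_equal(nNodes(buildSubstructureGraph(parseSmiles("CC"))), 1)
})
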
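test_that("Kd to pKd transform matches the closed form and is decreasing", {
  expect_equal(kdToPkd(1e9), 0)
  expect_equal(kdToPkd(1e4), 5)
  expect_equal(kdToPkd(1), 9)
  kd <- 10^seq(-2, 9, length.out = 30)
  expect_true(all(diff(kdToPkd(kd)) < 0))
  expect_error(kdToPkd(0), "positive")
  expect_error(kdToPkd(-5), "positive")
})

test_that("triples CSV round-trips records exactly", {
  recs <- generateSyntheticDataset(n_drugs = 4, n_proteins = 3,
                                   n_records = 6, noise_sd = 0.1, seed = 2)
  f <- tempfile(fileext = ".csv")
  writeTriplesCsv(recs, f)
  back <- loadDataset(f, "triples_csv")
  expect_equal(back$smiles, recs$smiles)
  expect_equal(back$sequence, recs$sequence)
  expect_equal(back$affinity, recs$affinity, tolerance = 1e-12)
  expect_error(loadDataset(tempfile(), "triples_csv"), "not found")
})

test_that("matrix-style layout loads row-major and skips the sentinel", {
  dir <- tempfile()
  dir.create(dir)
  writeLines(c("d1\tCC", "d2\tCCO"), file.path(dir, "compounds.txt"))
  writeLines(c("p1\tMKV", "p2\tACDE"), file.path(dir, "proteins.txt"))
  writeLines(c("5.0\tNA", "6.0\t7.5"), file.path(dir, "affinities.tsv"))
  recs <- loadDataset(dir, "matrix_style")
  expect_equal(nrow(recs), 3)
  expect_equal(recs$drug_id, c("d1", "d2", "d2"))      # row-major order
  expect_equal(recs$affinity, c(5.0, 6.0, 7.5))
  # pKd transform applies to raw Kd layouts
  rec2 <- loadDataset(dir, "matrix_style", transform = "pkd")
  expect_equal(rec2$affinity, -log10(c(5.0, 6.0, 7.5) / 1e9))
})

test_that("dataset loading names the offending compound on bad SMILES", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("drug_id,smiles,protein_id,sequence,affinity",
               "d1,CC,p1,MKV,5.0",
               "d2,notasmiles(,p1,MKV,6.0"), f)
  expect_error(loadDataset(f, "triples_csv"), "d2")
})

test_that("six-part split partitions any n with near-equal parts", {
  sp <- splitDataset(12, seed = 1)
  expect_true(all(lengths(sp$parts) == 2))

  sp13 <- splitDataset(13, seed = 1)
  expect_setequal(lengths(sp13$parts), c(3, 2))
  expect_equal(sum(lengths(sp13$parts) == 3), 1)

  expect_identical(splitDataset(50, seed = 7), splitDataset(50, seed = 7))
  expect_error(splitDataset(5), ">= 6")

  set.seed(99)
  for (n in sample(6:200, 8)) {
    sp <- splitDataset(n, seed = n)
    all_idx <- unlist(sp$parts)
    expect_equal(sort(all_idx), seq_len(n))          # disjoint cover
    expect_lte(diff(range(lengths(sp$parts))), 1)    # sizes differ <= 1
    expect_identical(sp$test, sp$parts[[1]])
    expect_length(sp$folds, 5)
  }
})

test_that("synthetic molecules parse, stay small and label deterministically", {
  recs <- generateSyntheticDataset(n_drugs = 15, n_proteins = 5,
                                   n_records = 50, noise_sd = 0, seed = 1)
  expect_equal(nrow(recs), 50)
  for (smi in unique(recs$smiles)) {
    mol <- parseSmiles(smi)
    expect_lte(countHeavyAtoms(mol), 40)
  }
  lens <- nchar(unique(recs$sequence))
  expect_true(all(lens >= 50 & lens <= 300))

  again <- generateSyntheticDataset(n_drugs = 15, n_proteins = 5,
                                    n_records = 50, noise_sd = 0, seed = 1)
  expect_identical(recs, again)

  noisy1 <- generateSyntheticDataset(8, 4, 20, noise_sd = 0.3, seed = 9)
  noisy2 <- generateSyntheticDataset(8, 4, 20, noise_sd = 0.3, seed = 9)
  expect_identical(noisy1$affinity, noisy2$affinity)
})

test_that("noise-free labels equal the documented descriptor formula", {
  recs <- generateSyntheticDataset(n_drugs = 10, n_proteins = 4,
                                   n_records = 25, noise_sd = 0, seed = 4)
  recomputed <- vapply(seq_len(nrow(recs)), function(i)
    syntheticAffinity(recs$smiles[i], recs$sequence[i]), numeric(1))
  expect_equal(recs$affinity, recomputed, tolerance = 1e-12)
  # and the formula itself decomposes into the documented descriptors
  mol <- parseSmiles(recs$smiles[1])
  expect_equal(syntheticAffinity(mol, recs$sequence[1]),
               4 + 0.6 * countAromaticRings(mol) +
                 0.8 * countHeavyAtoms(mol) / 10 +
                 2 * hydrophobicFraction(recs$sequence[1]))
})

test_that("molecular descriptors match hand counts", {
  expect_equal(countAromaticRings(parseSmiles("c1ccccc1-c1ccccc1")), 2)
  expect_equal(countAromaticRings(parseSmiles("C1CCCCC1")), 0)
  expect_equal(countHeavyAtoms(parseSmiles("CC(=O)O")), 4)
  expect_equal(hydrophobicFraction("AVLD"), 0.75)
  expect_equal(hydrophobicFraction("DDDD"), 0)
})
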
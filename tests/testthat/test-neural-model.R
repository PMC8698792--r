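test_that("adjacency normalization matches hand calculations", {
  expect_equal(normalizeAdjacency(matrix(0, 1, 1)), matrix(1, 1, 1))
  expect_equal(normalizeAdjacency(matrix(c(0, 1, 1, 0), 2)),
               matrix(0.5, 2, 2))
  K3 <- matrix(1, 3, 3) - diag(3)
  expect_equal(normalizeAdjacency(K3), matrix(1 / 3, 3, 3))
  expect_error(normalizeAdjacency(diag(2)), "diagonal")
})

test_that("node attention is a row-stochastic mixture in feature space", {
  set.seed(2)
  X <- matrix(rnorm(5 * 7), 5, 7)
  Wq <- matrix(rnorm(7 * 3), 7, 3)
  Wk <- matrix(rnorm(7 * 3), 7, 3)
  H0 <- nodeAttention(X, Wq, Wk)
  alpha <- attr(H0, "alpha")
  expect_equal(unname(rowSums(alpha)), rep(1, 5))
  expect_equal(dim(H0), dim(X))

  # single node: attention is the identity
  X1 <- matrix(rnorm(7), 1, 7)
  expect_equal(unname(nodeAttention(X1, Wq, Wk)), unname(X1),
               ignore_attr = TRUE)

  # zero projections: uniform weights, every row the column mean
  H0u <- nodeAttention(X, 0 * Wq, 0 * Wk)
  expect_equal(unname(H0u[1, ]), unname(colMeans(X)), ignore_attr = TRUE)
  expect_equal(max(abs(sweep(H0u, 2, colMeans(X)))), 0, tolerance = 1e-12)
})

test_that("the GCN layer equals explicit per-node message passing", {
  set.seed(4)
  for (rep in 1:5) {
    n <- sample(2:10, 1)
    A <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {                # random connected-ish graph
      cand <- setdiff(seq_len(n), i)
      j <- if (length(cand) == 1) cand else sample(cand, 1)
      A[i, j] <- A[j, i] <- 1
    }
    An <- normalizeAdjacency(A)
    H <- matrix(rnorm(n * 6), n, 6)
    W <- matrix(rnorm(6 * 4), 6, 4)
    expect_equal(gcnLayer(H, An, W), oracle_gcn_forward(H, An, W),
                 tolerance = 1e-12)
    expect_equal(gcnLayer(H, An, W, activation = "identity"),
                 oracle_gcn_forward(H, An, W, relu = FALSE),
                 tolerance = 1e-12)
  }
  # W = identity, identity activation: pure propagation
  An <- normalizeAdjacency(matrix(c(0, 1, 1, 0), 2))
  H <- matrix(c(1, 2, 3, 4), 2)
  expect_equal(gcnLayer(H, An, diag(2), activation = "identity"), An %*% H)
  expect_error(gcnLayer(H, An, matrix(0, 3, 2)), "mismatch")
})

test_that("graph branch embeds any graph to the configured width,
           invariant to node relabeling", {
  cfg <- tiny_config()
  params <- initParameters(cfg)
  g <- buildAtomGraph(parseSmiles("CCc1ccccc1O"))
  out <- graphBranchForward(g, params, cfg)
  expect_length(out, cfg$branch_dim)
  expect_true(all(is.finite(out)))

  # permuting the nodes leaves the embedding unchanged
  n <- nNodes(g)
  set.seed(6)
  perm <- sample(n)
  gp <- new("AtomGraph", adjacency = g@adjacency[perm, perm],
            features = g@features[perm, ], smiles = g@smiles)
  expect_equal(graphBranchForward(gp, params, cfg), out, tolerance = 1e-9)

  # single-node graph is fine
  g1 <- buildAtomGraph(parseSmiles("C"))
  expect_length(graphBranchForward(g1, params, cfg), cfg$branch_dim)

  # substructure graphs route through their own parameters
  sg <- buildSubstructureGraph(parseSmiles("CCc1ccccc1O"))
  expect_length(graphBranchForward(sg, params, cfg), cfg$branch_dim)
})

test_that("protein branch embeds encoded sequences deterministically", {
  cfg <- tiny_config()
  params <- initParameters(cfg)
  e <- encodeProtein("MKVLAWCDEF", L = cfg$protein_length)
  out <- proteinBranchForward(e, params, cfg)
  expect_length(out, cfg$branch_dim)
  expect_true(all(is.finite(out)))
  expect_identical(proteinBranchForward(e, params, cfg), out)

  # all-padding input is degenerate but defined
  pad <- integer(cfg$protein_length)
  expect_true(all(is.finite(proteinBranchForward(pad, params, cfg))))
})

test_that("fusion head concatenates three branch vectors to one scalar", {
  cfg <- tiny_config()
  params <- initParameters(cfg)
  nb <- cfg$branch_dim
  set.seed(8)
  P <- rnorm(nb); Am <- rnorm(nb); Cq <- rnorm(nb)
  expect_equal(nrow(params$f_fc1_W), 3 * nb)
  pred <- fusePredict(P, Am, Cq, params)
  expect_length(pred, 1)
  expect_true(is.finite(pred))
  expect_error(fusePredict(P[-1], Am, Cq, params), "width")

  # zero weights: the output is exactly the final bias
  zero <- params
  for (nm in grep("^f_", names(zero), value = TRUE)) zero[[nm]] <- 0 * zero[[nm]]
  zero$f_out_b <- 1.25
  expect_equal(fusePredict(P, Am, Cq, zero), 1.25)
})

test_that("analytic gradients agree with finite differences end to end", {
  cfg <- modelConfig(batch_size = 2, learning_rate = 0.01, epochs = 1,
                     dropout = 0, embedding_dim = 4, protein_length = 12,
                     conv_filters = c(4, 4, 4), conv_kernels = c(3, 3, 3),
                     protein_fc_hidden = 8, branch_dim = 6,
                     gcn_dims_atom = c(8, 8, 8), gcn_dims_sub = c(8, 8, 8),
                     graph_fc_hidden = 8, attention_dk = 4,
                     fc_hidden = c(8, 4), seed = 42)
  # full-length sequence: no zero-padding, so no ReLU kinks at exactly zero
  rec <- data.frame(smiles = "c1ccccc1C", sequence = "ACDEFGHIKMVW",
                    affinity = 6.2, stringsAsFactors = FALSE)
  feats <- DualGraphDTA:::.featurizeRecords(rec, cfg)
  params <- initParameters(cfg)
  params$f_out_b <- 6

  fwd <- DualGraphDTA:::.forwardRecord(rec$smiles, rec$sequence, params,
                                       cfg, feats, cache = TRUE)
  gr <- DualGraphDTA:::.backwardRecord(2 * (fwd$pred - rec$affinity), fwd,
                                       params, cfg)
  loss <- function(p)
    (DualGraphDTA:::.forwardRecord(rec$smiles, rec$sequence, p, cfg,
                                   feats)$pred - rec$affinity)^2
  set.seed(7)
  eps <- 1e-5
  for (nm in names(gr)) {
    for (ii in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
      up <- params; up[[nm]][ii] <- up[[nm]][ii] + eps
      dn <- params; dn[[nm]][ii] <- dn[[nm]][ii] - eps
      num <- (loss(up) - loss(dn)) / (2 * eps)
      expect_equal(gr[[nm]][ii], num, tolerance = 1e-4,
                   info = paste("gradient of", nm))
    }
  }
})

test_that("training is seed-deterministic and reduces the loss", {
  recs <- generateSyntheticDataset(n_drugs = 4, n_proteins = 4,
                                   n_records = 6, noise_sd = 0, seed = 3)
  cfg <- tiny_config(epochs = 30L)
  m1 <- trainModel(recs, cfg)
  m2 <- trainModel(recs, cfg)
  h1 <- trainingHistory(m1)
  expect_identical(h1, trainingHistory(m2))
  expect_lt(h1$train_mse[nrow(h1)], h1$train_mse[1])
  expect_true(all(is.finite(h1$train_mse)))

  # validation tracking keeps the best parameters
  val <- generateSyntheticDataset(4, 4, 5, noise_sd = 0, seed = 13)
  mv <- trainModel(recs, tiny_config(epochs = 10L), validation = val)
  hv <- trainingHistory(mv)
  expect_true("val_mse" %in% names(hv))
  expect_equal(min(hv$val_mse) <= hv$val_mse[nrow(hv)], TRUE)

  # unfeaturizable records are named
  bad <- recs
  bad$smiles[2] <- "notasmiles("
  expect_error(trainModel(bad, cfg), "notasmiles")
})

test_that("prediction is deterministic and checkpoints round-trip", {
  recs <- generateSyntheticDataset(n_drugs = 4, n_proteins = 3,
                                   n_records = 6, noise_sd = 0, seed = 5)
  m <- trainModel(recs, tiny_config(epochs = 15L))
  p1 <- predictAffinity(m, recs$smiles[1], recs$sequence[1])
  expect_true(is.finite(p1))
  expect_identical(predictAffinity(m, recs$smiles[1], recs$sequence[1]), p1)

  f <- tempfile(fileext = ".yaml")
  saveModel(m, f)
  m2 <- loadModel(f)
  expect_equal(predictAffinity(m2, recs$smiles[1], recs$sequence[1]), p1,
               tolerance = 1e-12)
  expect_equal(trainingHistory(m2)$train_mse, trainingHistory(m)$train_mse,
               tolerance = 1e-12)
  bad <- tempfile(fileext = ".yaml")
  writeLines("x: 1", bad)
  expect_error(loadModel(bad), "checkpoint")
})

test_that("attention scores are min-max normalized node importances", {
  recs <- generateSyntheticDataset(n_drugs = 3, n_proteins = 2,
                                   n_records = 4, noise_sd = 0, seed = 6)
  m <- trainModel(recs, tiny_config(epochs = 5L))
  g <- buildAtomGraph(parseSmiles("CCc1ccccc1O"))
  s <- attentionScores(m, g)
  expect_length(s, nNodes(g))
  expect_equal(max(s), 1)
  expect_equal(min(s), 0)
  expect_true(all(s >= 0 & s <= 1))

  # single node: score 1
  expect_equal(attentionScores(m, buildAtomGraph(parseSmiles("C"))), 1)

  # zero projections: uniform attention, all scores collapse to 1
  mu <- m
  mu@best_params$a_Wq <- 0 * mu@best_params$a_Wq
  mu@best_params$a_Wk <- 0 * mu@best_params$a_Wk
  expect_equal(attentionScores(mu, g), rep(1, nNodes(g)))

  # substructure graphs use the substructure branch attention
  sg <- buildSubstructureGraph(parseSmiles("CCc1ccccc1O"))
  expect_length(attentionScores(m, sg), nNodes(sg))
})
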
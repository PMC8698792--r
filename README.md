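# DualGraphDTA

Drug–target binding-affinity prediction in R, for computational chemists and
method developers who want an inspectable, dependency-light implementation of
a dual-graph neural affinity model.

Drug–target affinity (DTA) prediction treats the strength of binding between
a small molecule and a protein as a continuous regression target — the
log-transformed dissociation constant `pKd = −log10(Kd / 1e9)` (Kd in nM) or
a composite score such as KIBA. DualGraphDTA encodes each side of the pair
explicitly:

* **Drug, atom level.** The SMILES string is parsed into a molecular graph;
  each atom gets a 101-dimensional one-hot descriptor (element symbol,
  degree, total/implicit hydrogens, total valence, formal charge,
  aromaticity, ring membership).
* **Drug, substructure level.** The molecule is segmented into substructures:
  every bond outside any ring, and every ring cluster obtained by merging
  simple rings that share ≥ 3 atoms. Each substructure is a node with a
  35-dimensional descriptor (atom count, neighbour count, hydrogen count,
  ring flag, non-ring-bond flag); nodes are adjacent when their atom sets
  intersect. The canonical fragment keys form a reusable
  `SubstructureVocabulary`.
* **Protein.** Amino acids are tokens; GloVe-style embeddings are pretrained
  from corpus co-occurrence statistics (window 5, 1/distance weighting) and
  feed a three-layer 1D CNN over the length-1000 encoded sequence.

Both graphs pass through scaled dot-product node attention
(`H0 = softmax(XWq (XWk)ᵀ / √dk) X`) and three graph-convolution layers
(`H^(l+1) = σ(D̃^-1/2 Ã D̃^-1/2 H^(l) W^(l))`, Ã = A + I), then max pooling and
fully connected layers, giving three 128-dimensional embeddings (protein P,
atom graph Am, substructure graph Cq). Their concatenation
`T = P ⊕ Am ⊕ Cq ∈ R^384` is mapped 384 → 1024 → 512 → 1 to the affinity.
Training minimizes MSE with Adam; evaluation reports MSE, concordance index
(ties in predictions score 0.5), Pearson and Spearman correlations. A
screening interface ranks a molecule library against one target, and
per-node attention scores (min–max normalized) highlight influential atoms
and substructures.

The forward and backward passes are written out in base R matrix algebra and
validated against finite differences; chemistry parsing and canonical SMILES
go through ChemmineR/ChemmineOB (OpenBabel), FASTA through Biostrings.

## Worked example

```r
library(DualGraphDTA)

# a small synthetic benchmark: fragment-grammar drugs, random proteins,
# affinity = smooth descriptor function + Gaussian noise
recs <- generateSyntheticDataset(n_drugs = 50, n_proteins = 20,
                                 n_records = 500, noise_sd = 0.2, seed = 5)
sp    <- splitDataset(recs, seed = 5)           # 6 parts: test + 5 CV folds
train <- recs[unlist(sp$folds), ]
test  <- recs[sp$test, ]

cfg <- modelConfig(batch_size = 32, learning_rate = 0.002, epochs = 30,
                   dropout = 0.1, embedding_dim = 8, protein_length = 300,
                   conv_filters = c(8, 8, 8), conv_kernels = c(8, 8, 3),
                   protein_fc_hidden = 32, branch_dim = 16,
                   gcn_dims_atom = c(16, 16, 32),
                   gcn_dims_sub = c(16, 16, 32), graph_fc_hidden = 32,
                   attention_dk = 8, fc_hidden = c(64, 32), seed = 17)
model <- trainModel(train, cfg)

preds <- predictBatch(model, test)
unlist(evaluatePredictions(test$affinity, preds))
#>        mse         ci    pearson   spearman
#> 0.04742478 0.90131956 0.95360638 0.94405184
```

Held-out MSE ≈ 0.047 against ≈ 0.43 for the mean predictor: the network
recovers the synthetic affinity function well above chance, with a
concordance index of ≈ 0.90. (`modelConfig()` with no arguments gives the
full published widths — 128-dimensional branches, 1000/256/32 CNN filters,
1024/512 fusion layers — which want GPU-scale budgets to train.)

Molecule-side objects are first-class:

```r
mol <- parseSmiles("c1ccccc1-c1ccccc1")   # biphenyl
segmentSubstructures(mol, keys = FALSE)   # 2 rings + 1 connecting bond
buildSubstructureGraph(mol)               # ring - bond - ring path
attentionScores(model, buildAtomGraph(mol))
```

A command-line tool wraps the same functions
(`Rscript inst/cli/dualgraphdta.R <subcommand>`, or the installed copy under
`system.file("cli", "dualgraphdta.R", package = "DualGraphDTA")`) with
subcommands `pretrain-embeddings`, `build-vocab`, `train`, `evaluate`,
`predict`, `screen` and `make-synthetic`.

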
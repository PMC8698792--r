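---
title: "The dual-graph affinity model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dual-graph affinity model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DualGraphDTA)
```

## The problem and the model

Drug–target affinity (DTA) prediction is a regression problem: given a small
molecule (as SMILES) and a protein (as an amino-acid sequence), predict a
continuous binding-affinity label — here the log-transformed dissociation
constant, `pKd = −log10(Kd / 1e9)` with Kd in nanomolar (`kdToPkd()`), or a
KIBA-style composite score used as-is. The model assumes nothing about the
label beyond it being a finite real on a roughly unit-to-ten scale.

The network has three encoder branches and a fusion head:

1. **Atom-level graph branch.** Heavy atoms are nodes, bonds are unlabeled
   edges. Each atom carries a 101-dimensional binary descriptor.
2. **Substructure-level graph branch.** The molecule is segmented into
   chemically meaningful fragments (see below); each fragment is a node with
   a 35-dimensional binary descriptor, and fragments sharing at least one
   atom are adjacent.
3. **Protein CNN branch.** The sequence is tokenized per residue, embedded
   through a (pretrainable) lookup table, and passed through three 1D
   convolutions, global max pooling and two dense layers.

Each graph branch applies scaled dot-product node attention
`α = softmax((X Wq)(X Wk)ᵀ / √dk)`, `H⁽⁰⁾ = α X`, followed by three graph
convolution layers `H⁽ˡ⁺¹⁾ = ReLU(D̃^{-1/2} Ã D̃^{-1/2} H⁽ˡ⁾ W⁽ˡ⁾)` with
`Ã = A + I`, column-wise max pooling over nodes, and two dense layers. All
three branches end in a `branch_dim`-wide embedding (128 by default); the
concatenated 384-vector passes through dense layers 384 → 1024 → 512 → 1.
Training minimizes mean squared error with Adam.

The attention stays in feature space deliberately: there is no value
projection, so `H⁽⁰⁾` is an attention-weighted mixture of the original node
features and the no-attention model (`H⁽⁰⁾ = X`) is recovered exactly by
zeroing `Wq` and `Wk`. The query/key width `dk` (default 64) only controls
the expressiveness of the weighting. The two graph branches have independent
attention and GCN parameters; nothing in the architecture forces the atom
and substructure views to share geometry, and tying them would couple the
101- and 35-dimensional feature spaces for no clear benefit.

## Molecule segmentation

A substructure is either

* a **ring cluster** — a simple ring, or the fixpoint of merging simple
  rings that pairwise share ≥ 3 atoms (fused systems such as norbornane
  merge; ortho-fused aromatics such as naphthalene, sharing 2 atoms, do
  not), or
* a **non-ring bond** — a pair of atoms joined by a bond that lies on no
  cycle, or
* a degenerate **single atom**, emitted only for atoms with no bonds, so
  that every molecule has a non-empty substructure graph for pooling.

Merging is iterated to a fixpoint rather than in one pairwise pass: one pass
can leave two already-merged clusters that now share ≥ 3 atoms, and the
fixpoint guarantees the postcondition that no two emitted ring clusters
share 3 or more atoms.

Simple rings are perceived as the smallest ring through each ring bond
(breadth-first search for the shortest alternate path between the bond's
endpoints), deduplicated. On drug-scale molecules this coincides with the
symmetrized smallest-set-of-smallest-rings; the test suite checks
equivalence against an independent oracle that enumerates *all* simple
cycles by depth-first search on molecules of up to 8 heavy atoms, plus hand
counts for benzene (1 substructure), biphenyl (3), naphthalene (2) and
norbornane (1).

Substructure identity for the vocabulary is the canonical SMILES of the
extracted fragment (atoms of the substructure plus bonds among them;
severed attachment points are hydrogen-filled). This makes vocabulary
construction deterministic — the serialized TSV is byte-identical across
rebuilds — at the cost that fragments differing only in their environment
collapse to one key, which is the intended notion of a reusable fragment
vocabulary.

## Featurization layouts

The published contracts fix the feature *kinds* and the total widths (101
and 35); the slot allocation is this package's documented choice:

* atoms: element symbol one-hot over a fixed 43-symbol list + "other" (44),
  degree 0–10 (11), total hydrogens 0–10 (11), implicit hydrogens 0–10 (11),
  total valence 0–10 (11), formal charge −5…+5 (11), aromatic flag (1),
  in-ring flag (1). Counts outside a range clamp to the last slot.
* substructures: atom count 0–10 (11), neighbouring-substructure count 0–10
  (11), total hydrogens 0–10 (11), contains-ring flag (1),
  contains-non-ring-bond flag (1). "Edges connected to the substructure" is
  read as the number of neighbouring substructures in the substructure
  graph.

Every atom row sums to 6, 7 or 8 (six one-hots plus up to two flags) and
every substructure row to 3, 4 or 5 — both enforced as validity conditions
and tested. Atom indices are 1-based inside the package (R convention);
the vocabulary TSV uses 0-based ids as its external contract. Bond-type
edge features and stereochemistry are out of scope: edges are unlabeled.

## Protein embeddings

Each amino acid is one token: the 20 standard letters plus "X" for anything
else, with index 0 reserved for padding. Co-occurrence is accumulated within
a sliding window (default 5 residues) at weight 1/distance, symmetrically,
never across sequence records. The embedding trainer minimizes the weighted
least-squares objective `Σ f(x_ij)(w_i·u_j + b_i + c_j − log x_ij)²` with
`f(x) = min(1, (x/x_max)^0.75)`, `x_max = 100`, by per-cell AdaGrad updates
(initial step 0.05) over the non-zero cells — the standard co-occurrence
factorization recipe, with the final embedding the sum of word and context
vectors. Dimensionality, window, weighting and optimizer are this package's
defaults (d = 128, overridable everywhere) since only the approach, not the
hyperparameters, is fixed upstream. Sequences are encoded to exactly
`L = 1000` indices (truncate, then right-pad with 0); the padding row of the
embedding table is held at zero during training by zeroing its gradient.

With a 21-token vocabulary the co-occurrence matrix is tiny, so pretraining
is cheap at any corpus size; the full-scale UniRef50 corpus is an interface
target (FASTA in, TSV out), while tests and examples use synthetic corpora.

## Training: numerical choices

* **Initialization**: Glorot-uniform weights, zero biases, seeded. The
  output bias starts at the mean training label so the first epochs are not
  spent learning the intercept.
* **Optimizer**: Adam, β₁ = 0.9, β₂ = 0.999, ε = 1e-8; published defaults
  are batch 512, learning rate 5e-4, 1500 epochs, dropout 0.2.
* **Dropout** is applied in the two fusion hidden layers (inverted dropout,
  disabled at prediction time). Branch layers are left undropped; at desk
  scale the fusion head is where co-adaptation shows first.
* **Model selection**: when a validation set is supplied, the parameters at
  the epoch with the lowest validation MSE are kept alongside the final
  ones; prediction uses the best-validation parameters. No early stopping.
* **Determinism**: one seed controls initialization, shuffling, dropout and
  the synthetic generators; identical seeds give bit-identical loss traces.
* **Gradients** are hand-derived analytic expressions (attention softmax,
  GCN propagation, convolution window unrolling, max-pool routing) and are
  compared with central finite differences end to end in the suite. The
  gradient-check fixture uses a full-length sequence on purpose: zero
  padding creates pre-activations exactly at the ReLU kink where a
  subgradient and a finite difference legitimately disagree.
* **Degenerate inputs**: single-node graphs pass through attention as the
  identity; all-padding protein input is defined (zero embedding rows);
  max-pool ties break toward the first node, which only matters for exact
  reproducibility, not correctness.

## Metrics

MSE, concordance index, Pearson and Spearman. The concordance index sums a
three-valued step over all ordered pairs with distinct true labels —
1 for a correctly ordered prediction pair, 0.5 for a predicted tie, 0
otherwise — normalized by the number of such pairs; pairs tied in the true
label are excluded from numerator and denominator (the sum runs strictly
over larger-vs-smaller true values). Spearman uses the classical
`1 − 6Σd²/(n(n²−1))` rank-difference form when ranks are tie-free and
Pearson-of-average-ranks otherwise, since the closed form assumes distinct
ranks. Both correlations refuse constant vectors (σ = 0) rather than
returning NaN.

## The synthetic benchmark

`generateSyntheticDataset()` exists so every stage is testable without
downloads. Drugs are assembled from a closed fragment grammar — aromatic and
aliphatic rings, short chains, an optional terminal halogen — which
guarantees parseable SMILES with at most 40 heavy atoms (matching the
heavy-atom budget used for screening libraries). Proteins are uniform random
sequences over the 20 standard residues, lengths 50–300. The label is

affinity = 4 + 0.6·(aromatic rings) + 0.8·(heavy atoms)/10 +
2·(hydrophobic residue fraction) + N(0, noise_sd),

with hydrophobic = {A, C, F, I, L, M, V, W}; the coefficients were chosen
once to span a realistic pKd-like 4–10 range with the molecular and protein
terms contributing on comparable scales, and the default noise (sd 0.2) is
of the order of experimental affinity noise. All terms are recomputable from
the exported descriptors (`countAromaticRings()`, `countHeavyAtoms()`,
`hydrophobicFraction()`, `syntheticAffinity()`), which the tests use to
verify the noise-free labels exactly.

What the generator does *not* emulate: real binding is not an additive
function of three descriptors; there is no drug–protein interaction term, no
binding-site structure, no activity cliffs, and random sequences have none
of the statistics of real proteins. Passing the learning checks therefore
demonstrates that the architecture, gradients and training loop can recover
a smooth structure–activity signal from both molecule descriptors and
sequence composition — it says nothing about accuracy on real kinase
panels, which require the full-scale benchmarks and budgets.

## Problem sizes used in tests

The suite and the acceptance script run two training checks at reduced
widths (8-dimensional embeddings, 16-dimensional branches, 8-filter
convolutions, protein length 300): memorization of 10 noise-free records to
training MSE below 0.01, and a 500-record run (train on five folds, test on
the held-out part) where held-out MSE must beat the mean predictor. These
sizes were chosen as the smallest at which both phenomena are stable across
seeds; the full published configuration is exercised forward-only for the
dimension contracts.

## Screening and attention read-out

`screenRank()` scores a molecule library against one target, sorts stably
(ties keep input order) and returns the top k. The default direction is
descending — higher predicted affinity first, the natural reading for pKd
labels — with an `asc` option because a score trained on a loss-like scale
ranks the other way; the direction is a flag rather than a fixed convention.
Per-node importances are the column means of the attention matrix (how much
weight all nodes place on a node), min–max normalized so the most important
node scores 1.0 and the least 0.0; a single-node or uniform-attention graph
scores 1.0 everywhere.

## Known limitations

* Ring perception by smallest-ring-per-bond can differ from a minimum cycle
  basis on exotic cage systems where several equally small rings pass
  through every bond; irrelevant for drug-like chemistry and covered by the
  oracle tests on the fixture set.
* The CNN protein branch sees composition and local motifs, not long-range
  structure; length-1000 truncation discards the tail of very long
  sequences.
* Dense matrices throughout: fine for molecules (≤ ~200 atoms) and
  desk-scale training, not tuned for GPU-scale corpora.
* Checkpoints serialize every tensor to YAML text; exact to 17 significant
  digits, but large models produce large files.
* KIBA-score construction from Ki/Kd/IC50 and cold-drug/cold-target splits
  are out of scope; the 6-part split is at the record level.
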
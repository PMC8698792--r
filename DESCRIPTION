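Package: DualGraphDTA
Title: Drug-Target Binding Affinity Prediction from Dual-Level Molecular
    Graphs and Pretrained Amino-Acid Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts continuous drug-target binding affinities (pKd or KIBA
    scores) by encoding each drug molecule as two graphs - an atom-level graph
    with 101-dimensional one-hot node features and a substructure-level graph
    over segmented ring/bond fragments with 35-dimensional node features -
    processed by attention-augmented graph convolutional networks, and each
    protein sequence via GloVe-style pretrained amino-acid embeddings followed
    by a 1D convolutional encoder. The three 128-dimensional branch embeddings
    are fused by fully connected layers into a scalar affinity. Includes the
    molecule segmentation algorithm and substructure vocabulary, the embedding
    pretrainer, regression metrics (MSE, concordance index, Pearson, Spearman),
    dataset I/O and splitting utilities, a synthetic benchmark generator, and a
    virtual-screening ranking interface with per-node attention scores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    Biostrings,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
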
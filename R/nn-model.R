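# The affinity network: two attention-GCN graph branches (atom level and
# substructure level), a convolutional protein branch, and a fully connected
# fusion head ending in one scalar. Forward and analytic backward passes are
# written out explicitly; the finite-difference test in the suite checks the
# gradients end to end.

#' Model and optimization configuration
#'
#' Returns the full hyperparameter set with the published defaults: batch
#' size 512, learning rate 5e-4, 1500 epochs, dropout 0.2, Adam; protein CNN
#' filter counts (1000, 256, 32) with kernel sizes (8, 8, 3); three GCN
#' layers per graph branch with input dims (N, N, 2N) and output dims
#' (N, 2N, 4N) where N is the node-feature width (101 for atoms, 35 for
#' substructures); fusion hidden sizes (1024, 512); protein input length
#' 1000. Reduced values of any argument give a smaller model for desk-scale
#' experiments.
#'
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param epochs training epochs.
#' @param dropout dropout rate in the fusion head hidden layers.
#' @param embedding_dim amino-acid embedding dimensionality.
#' @param protein_length fixed encoded protein length L.
#' @param conv_filters,conv_kernels protein CNN filter counts / kernel sizes.
#' @param protein_fc_hidden hidden width of the first protein FC layer.
#' @param branch_dim output width of every branch (128).
#' @param atom_feature_dim,sub_feature_dim node-feature widths (101 / 35).
#' @param gcn_dims_atom,gcn_dims_sub optional integer vectors of the three
#'   GCN output dims; `NULL` applies the (N, 2N, 4N) rule.
#' @param graph_fc_hidden hidden width of the post-pooling graph FC layer.
#' @param attention_dk query/key projection width of the node attention.
#' @param fc_hidden the two fusion hidden widths.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return named list of class-checked hyperparameters.
#' @export
modelConfig <- function(batch_size = 512, learning_rate = 5e-4,
                        epochs = 1500, dropout = 0.2,
                        embedding_dim = 128, protein_length = 1000,
                        conv_filters = c(1000, 256, 32),
                        conv_kernels = c(8, 8, 3),
                        protein_fc_hidden = 1024, branch_dim = 128,
                        atom_feature_dim = 101, sub_feature_dim = 35,
                        gcn_dims_atom = NULL, gcn_dims_sub = NULL,
                        graph_fc_hidden = 1024, attention_dk = 64,
                        fc_hidden = c(1024, 512), seed = 1L) {
  cfg <- list(batch_size = as.integer(batch_size),
              learning_rate = learning_rate, epochs = as.integer(epochs),
              dropout = dropout, embedding_dim = as.integer(embedding_dim),
              protein_length = as.integer(protein_length),
              conv_filters = as.integer(conv_filters),
              conv_kernels = as.integer(conv_kernels),
              protein_fc_hidden = as.integer(protein_fc_hidden),
              branch_dim = as.integer(branch_dim),
              atom_feature_dim = as.integer(atom_feature_dim),
              sub_feature_dim = as.integer(sub_feature_dim),
              gcn_dims_atom = if (is.null(gcn_dims_atom)) NULL
                              else as.integer(gcn_dims_atom),
              gcn_dims_sub = if (is.null(gcn_dims_sub)) NULL
                             else as.integer(gcn_dims_sub),
              graph_fc_hidden = as.integer(graph_fc_hidden),
              attention_dk = as.integer(attention_dk),
              fc_hidden = as.integer(fc_hidden),
              seed = as.integer(seed))
  stopifnot(cfg$batch_size > 0, cfg$learning_rate > 0, cfg$epochs >= 0,
            cfg$dropout >= 0, cfg$dropout < 1,
            length(cfg$conv_filters) == 3, length(cfg$conv_kernels) == 3,
            length(cfg$fc_hidden) == 2, cfg$branch_dim > 0,
            cfg$attention_dk > 0)
  cfg
}

.gcnDims <- function(N, override) {
  if (!is.null(override)) {
    stopifnot(length(override) == 3)
    return(list(d_in = c(N, override[1], override[2]), d_out = override))
  }
  list(d_in = c(N, N, 2L * N), d_out = c(N, 2L * N, 4L * N))
}

# initialize one graph branch's parameters, names prefixed "a_" or "s_"
.initGraphBranch <- function(prefix, N, cfg) {
  dims <- .gcnDims(N, cfg[[paste0("gcn_dims_",
                                  if (prefix == "a") "atom" else "sub")]])
  p <- list()
  p[[paste0(prefix, "_Wq")]] <- .glorot(N, cfg$attention_dk)
  p[[paste0(prefix, "_Wk")]] <- .glorot(N, cfg$attention_dk)
  for (l in 1:3)
    p[[paste0(prefix, "_g", l, "_W")]] <- .glorot(dims$d_in[l], dims$d_out[l])
  p[[paste0(prefix, "_fc1_W")]] <- .glorot(dims$d_out[3], cfg$graph_fc_hidden)
  p[[paste0(prefix, "_fc1_b")]] <- numeric(cfg$graph_fc_hidden)
  p[[paste0(prefix, "_fc2_W")]] <- .glorot(cfg$graph_fc_hidden, cfg$branch_dim)
  p[[paste0(prefix, "_fc2_b")]] <- numeric(cfg$branch_dim)
  p
}

#' Initialize all model parameters
#'
#' Glorot-uniform weights and zero biases, seeded. The protein embedding
#' table is taken from `embedding` when given (e.g. pretrained with
#' [trainGlove()]) and is trainable either way; its padding row stays zero.
#'
#' @param config from [modelConfig()].
#' @param embedding optional pretrained embedding matrix whose row count is
#'   the vocabulary size + padding and whose column count must equal
#'   `config$embedding_dim`.
#' @return named list of parameter matrices/vectors.
#' @export
initParameters <- function(config, embedding = NULL) {
  set.seed(config$seed)
  V <- length(aminoAcidVocabulary()) + 1L   # + PAD row
  d <- config$embedding_dim
  p <- list()
  if (is.null(embedding)) {
    p$E <- .glorot(V, d)
    p$E[1, ] <- 0
  } else {
    stopifnot(nrow(embedding) == V, ncol(embedding) == d)
    p$E <- unname(embedding)
  }
  k <- config$conv_kernels; f <- config$conv_filters
  chans <- c(d, f[1], f[2])
  for (l in 1:3) {
    p[[paste0("p_conv", l, "_W")]] <- .glorot(k[l] * chans[l], f[l])
    p[[paste0("p_conv", l, "_b")]] <- numeric(f[l])
  }
  p$p_fc1_W <- .glorot(f[3], config$protein_fc_hidden)
  p$p_fc1_b <- numeric(config$protein_fc_hidden)
  p$p_fc2_W <- .glorot(config$protein_fc_hidden, config$branch_dim)
  p$p_fc2_b <- numeric(config$branch_dim)

  p <- c(p, .initGraphBranch("a", config$atom_feature_dim, config),
         .initGraphBranch("s", config$sub_feature_dim, config))

  h <- config$fc_hidden
  p$f_fc1_W <- .glorot(3L * config$branch_dim, h[1])
  p$f_fc1_b <- numeric(h[1])
  p$f_fc2_W <- .glorot(h[1], h[2])
  p$f_fc2_b <- numeric(h[2])
  p$f_out_W <- .glorot(h[2], 1L)
  p$f_out_b <- numeric(1)
  p
}

#' Symmetrically normalized adjacency with self-loops
#'
#' Computes `D^-1/2 (A + I) D^-1/2` where `D` is the degree matrix of
#' `A + I` — the propagation operator of a graph convolution layer.
#'
#' @param A symmetric binary adjacency matrix with zero diagonal.
#' @return dense real matrix of the same shape.
#' @examples
#' normalizeAdjacency(matrix(c(0, 1, 1, 0), 2))  # all entries 0.5
#' @export
normalizeAdjacency <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (any(diag(A) != 0)) stop("adjacency must have zero diagonal")
  if (!isTRUE(all.equal(A, t(A)))) stop("adjacency must be symmetric")
  At <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(At))
  At * outer(dinv, dinv)
}

#' Scaled dot-product node attention
#'
#' Computes `alpha = softmax((X Wq)(X Wk)^T / sqrt(dk))` row-wise and returns
#' `H0 = alpha X`: each node's input feature vector is replaced by an
#' attention-weighted mixture over all nodes, staying in feature space. The
#' attention matrix is attached as attribute `"alpha"`.
#'
#' @param X node-feature matrix (n x N).
#' @param Wq,Wk projection matrices (N x dk).
#' @return n x N matrix with attribute `alpha` (n x n, rows sum to 1).
#' @export
nodeAttention <- function(X, Wq, Wk) {
  stopifnot(is.matrix(X), nrow(Wq) == ncol(X), nrow(Wk) == ncol(X))
  res <- .attentionForward(X, Wq, Wk)
  out <- res$H0
  attr(out, "alpha") <- res$alpha
  out
}

.attentionForward <- function(X, Wq, Wk) {
  dk <- ncol(Wq)
  Q <- X %*% Wq
  K <- X %*% Wk
  S <- (Q %*% t(K)) / sqrt(dk)
  alpha <- .softmaxRows(S)
  list(H0 = alpha %*% X, alpha = alpha, Q = Q, K = K, dk = dk)
}

#' One graph convolution layer
#'
#' `sigma(A_norm H W)` with ReLU activation by default.
#'
#' @param H node representation matrix (n x d_in).
#' @param A_norm normalized adjacency from [normalizeAdjacency()].
#' @param W weight matrix (d_in x d_out).
#' @param activation "relu" or "identity".
#' @return n x d_out matrix.
#' @export
gcnLayer <- function(H, A_norm, W, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  if (ncol(H) != nrow(W)) stop("gcnLayer: dimension mismatch between H and W")
  if (nrow(H) != nrow(A_norm)) stop("gcnLayer: H and A_norm disagree on n")
  M <- A_norm %*% H %*% W
  if (activation == "relu") .relu(M) else M
}

# full graph-branch forward; p is the parameter list, prefix "a" or "s"
.graphForward <- function(A_norm, X, p, prefix, cache = FALSE) {
  g <- function(nm) p[[paste0(prefix, "_", nm)]]
  att <- .attentionForward(X, g("Wq"), g("Wk"))
  H0 <- att$H0
  M1 <- A_norm %*% H0 %*% g("g1_W"); G1 <- .relu(M1)
  M2 <- A_norm %*% G1 %*% g("g2_W"); G2 <- .relu(M2)
  M3 <- A_norm %*% G2 %*% g("g3_W"); G3 <- .relu(M3)
  pool <- .maxPool(G3)
  u <- matrix(pool$out, 1) %*% g("fc1_W") + matrix(g("fc1_b"), 1)
  z <- .relu(u)
  out <- z %*% g("fc2_W") + matrix(g("fc2_b"), 1)
  res <- list(out = drop(out))
  if (cache)
    res$cache <- list(A_norm = A_norm, X = X, att = att, H0 = H0,
                      M1 = M1, G1 = G1, M2 = M2, G2 = G2, M3 = M3, G3 = G3,
                      pool = pool, u = u, z = z)
  res
}

# backward through one graph branch; returns named gradient list
.graphBackward <- function(dout, cache, p, prefix) {
  g <- function(nm) p[[paste0(prefix, "_", nm)]]
  gr <- list()
  dout <- matrix(dout, 1)
  gr[[paste0(prefix, "_fc2_W")]] <- crossprod(cache$z, dout)
  gr[[paste0(prefix, "_fc2_b")]] <- drop(dout)
  dz <- dout %*% t(g("fc2_W"))
  du <- dz * (cache$u > 0)
  gr[[paste0(prefix, "_fc1_W")]] <- crossprod(matrix(cache$pool$out, 1), du)
  gr[[paste0(prefix, "_fc1_b")]] <- drop(du)
  dg <- drop(du %*% t(g("fc1_W")))
  dG3 <- .maxPoolBackward(dg, cache$pool$argmax, nrow(cache$G3))

  A <- cache$A_norm
  dM3 <- dG3 * (cache$M3 > 0)
  gr[[paste0(prefix, "_g3_W")]] <- crossprod(A %*% cache$G2, dM3)
  dG2 <- A %*% dM3 %*% t(g("g3_W"))
  dM2 <- dG2 * (cache$M2 > 0)
  gr[[paste0(prefix, "_g2_W")]] <- crossprod(A %*% cache$G1, dM2)
  dG1 <- A %*% dM2 %*% t(g("g2_W"))
  dM1 <- dG1 * (cache$M1 > 0)
  gr[[paste0(prefix, "_g1_W")]] <- crossprod(A %*% cache$H0, dM1)
  dH0 <- A %*% dM1 %*% t(g("g1_W"))

  att <- cache$att
  X <- cache$X
  dalpha <- dH0 %*% t(X)
  dS <- att$alpha * (dalpha - rowSums(dalpha * att$alpha))
  dQ <- dS %*% att$K / sqrt(att$dk)
  dK <- t(dS) %*% att$Q / sqrt(att$dk)
  gr[[paste0(prefix, "_Wq")]] <- crossprod(X, dQ)
  gr[[paste0(prefix, "_Wk")]] <- crossprod(X, dK)
  gr
}

# protein branch forward; x is the encoded index vector (0 = PAD)
.proteinForward <- function(x, p, cfg, cache = FALSE) {
  X <- p$E[x + 1L, , drop = FALSE]
  k <- cfg$conv_kernels
  c1 <- .convForward(X, p$p_conv1_W, p$p_conv1_b, k[1])
  c2 <- .convForward(c1$out, p$p_conv2_W, p$p_conv2_b, k[2])
  c3 <- .convForward(c2$out, p$p_conv3_W, p$p_conv3_b, k[3])
  pool <- .maxPool(c3$out)
  u <- matrix(pool$out, 1) %*% p$p_fc1_W + matrix(p$p_fc1_b, 1)
  z <- .relu(u)
  out <- z %*% p$p_fc2_W + matrix(p$p_fc2_b, 1)
  res <- list(out = drop(out))
  if (cache)
    res$cache <- list(x = x, X = X, c1 = c1, c2 = c2, c3 = c3,
                      pool = pool, u = u, z = z)
  res
}

.proteinBackward <- function(dout, cache, p, cfg) {
  k <- cfg$conv_kernels
  gr <- list()
  dout <- matrix(dout, 1)
  gr$p_fc2_W <- crossprod(cache$z, dout)
  gr$p_fc2_b <- drop(dout)
  dz <- dout %*% t(p$p_fc2_W)
  du <- dz * (cache$u > 0)
  gr$p_fc1_W <- crossprod(matrix(cache$pool$out, 1), du)
  gr$p_fc1_b <- drop(du)
  dg <- drop(du %*% t(p$p_fc1_W))
  dH3 <- .maxPoolBackward(dg, cache$pool$argmax, nrow(cache$c3$out))
  b3 <- .convBackward(dH3, cache$c3, p$p_conv3_W, k[3])
  gr$p_conv3_W <- b3$dW; gr$p_conv3_b <- b3$db
  b2 <- .convBackward(b3$dM, cache$c2, p$p_conv2_W, k[2])
  gr$p_conv2_W <- b2$dW; gr$p_conv2_b <- b2$db
  b1 <- .convBackward(b2$dM, cache$c1, p$p_conv1_W, k[1])
  gr$p_conv1_W <- b1$dW; gr$p_conv1_b <- b1$db
  dE <- matrix(0, nrow(p$E), ncol(p$E))
  agg <- rowsum(b1$dM, group = cache$x + 1L)
  dE[as.integer(rownames(agg)), ] <- agg
  dE[1, ] <- 0                      # padding row stays fixed at zero
  gr$E <- dE
  gr
}

# fusion head; drop rates 0 in eval mode
.fusionForward <- function(P, Am, Cq, p, dropout = 0, cache = FALSE) {
  T0 <- matrix(c(P, Am, Cq), 1)
  u1 <- T0 %*% p$f_fc1_W + matrix(p$f_fc1_b, 1)
  z1 <- .relu(u1)
  m1 <- if (dropout > 0)
    (stats::runif(length(z1)) >= dropout) / (1 - dropout) else 1
  z1d <- z1 * m1
  u2 <- z1d %*% p$f_fc2_W + matrix(p$f_fc2_b, 1)
  z2 <- .relu(u2)
  m2 <- if (dropout > 0)
    (stats::runif(length(z2)) >= dropout) / (1 - dropout) else 1
  z2d <- z2 * m2
  pred <- drop(z2d %*% p$f_out_W + p$f_out_b)
  res <- list(out = pred)
  if (cache)
    res$cache <- list(T0 = T0, u1 = u1, z1d = z1d, m1 = m1,
                      u2 = u2, z2d = z2d, m2 = m2)
  res
}

.fusionBackward <- function(dpred, cache, p) {
  gr <- list()
  gr$f_out_W <- t(cache$z2d) * dpred
  gr$f_out_b <- dpred
  dz2d <- dpred * t(p$f_out_W)
  dz2 <- dz2d * cache$m2
  du2 <- dz2 * (cache$u2 > 0)
  gr$f_fc2_W <- crossprod(cache$z1d, du2)
  gr$f_fc2_b <- drop(du2)
  dz1d <- du2 %*% t(p$f_fc2_W)
  dz1 <- dz1d * cache$m1
  du1 <- dz1 * (cache$u1 > 0)
  gr$f_fc1_W <- crossprod(cache$T0, du1)
  gr$f_fc1_b <- drop(du1)
  dT <- drop(du1 %*% t(p$f_fc1_W))
  n <- length(dT) / 3
  gr$.dP <- dT[1:n]
  gr$.dAm <- dT[(n + 1):(2 * n)]
  gr$.dCq <- dT[(2 * n + 1):(3 * n)]
  gr
}

#' Graph branch forward pass
#'
#' Node attention, three graph convolution layers, column-wise max pooling
#' over nodes, then two fully connected layers down to the branch embedding.
#'
#' @param graph an [AtomGraph-class] or [SubstructureGraph-class].
#' @param params parameter list from [initParameters()] (or a trained
#'   [DTAModel-class]'s parameters).
#' @param config the matching [modelConfig()].
#' @return numeric vector of length `config$branch_dim`.
#' @export
graphBranchForward <- function(graph, params, config) {
  if (!(is(graph, "AtomGraph") || is(graph, "SubstructureGraph")))
    stop("graph must be an AtomGraph or SubstructureGraph")
  if (nrow(graph@adjacency) < 1) stop("graph must have at least one node")
  prefix <- if (is(graph, "AtomGraph")) "a" else "s"
  A_norm <- normalizeAdjacency(graph@adjacency)
  .graphForward(A_norm, graph@features, params, prefix)$out
}

#' Protein branch forward pass
#'
#' Embedding lookup, three 1D convolutions with ReLU, global max pooling
#' over sequence positions, then two fully connected layers.
#'
#' @param encoded integer index vector from [encodeProtein()].
#' @param params parameter list.
#' @param config the matching [modelConfig()].
#' @return numeric vector of length `config$branch_dim`.
#' @export
proteinBranchForward <- function(encoded, params, config) {
  stopifnot(length(encoded) == config$protein_length)
  .proteinForward(as.integer(encoded), params, config)$out
}

#' Fuse branch embeddings and predict affinity
#'
#' Concatenates the three branch vectors (protein, atom graph, substructure
#' graph) and applies the fully connected head down to one scalar. Dropout is
#' disabled (evaluation mode).
#'
#' @param P,Am,Cq branch embeddings, each of length `branch_dim`.
#' @param params parameter list.
#' @return scalar predicted affinity.
#' @export
fusePredict <- function(P, Am, Cq, params) {
  nb <- nrow(params$f_fc1_W) / 3
  if (length(P) != nb || length(Am) != nb || length(Cq) != nb)
    stop("branch embedding width does not match the fusion head")
  .fusionForward(P, Am, Cq, params, dropout = 0)$out
}
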
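# Numerical building blocks for the network: initialization, activations,
# 1D convolution via window unrolling, and the Adam optimizer. All passes are
# plain dense matrix algebra with hand-derived analytic gradients (verified
# against finite differences in the test suite).

.glorot <- function(n_in, n_out) {
  limit <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -limit, limit), n_in, n_out)
}

.relu <- function(x) pmax(x, 0)

# row-wise softmax, numerically stabilized
.softmaxRows <- function(S) {
  if (!is.matrix(S)) S <- matrix(S, 1)
  m <- apply(S, 1, max)
  E <- exp(S - m)
  E / rowSums(E)
}

# unroll sliding windows of length k over the rows of M (T x C) into a
# (T-k+1) x (k*C) matrix; column blocks are ordered by window offset
.convWindows <- function(M, k) {
  T2 <- nrow(M) - k + 1
  if (T2 < 1) stop("sequence shorter than convolution kernel")
  do.call(cbind, lapply(0:(k - 1), function(o)
    M[(1 + o):(T2 + o), , drop = FALSE]))
}

# scatter window-space gradients back onto the conv input
.convWindowsBackward <- function(dZ, k, n_rows, n_cols) {
  dM <- matrix(0, n_rows, n_cols)
  T2 <- nrow(dZ)
  for (o in 0:(k - 1)) {
    block <- dZ[, (o * n_cols + 1):((o + 1) * n_cols), drop = FALSE]
    idx <- (1 + o):(T2 + o)
    dM[idx, ] <- dM[idx, ] + block
  }
  dM
}

# one 1D conv layer forward: M (T x C) -> list(out = relu(Z W + b), cache)
.convForward <- function(M, W, b, k) {
  Z <- .convWindows(M, k)
  A <- sweep(Z %*% W, 2, b, `+`)
  list(out = .relu(A), Z = Z, A = A, in_rows = nrow(M), in_cols = ncol(M))
}

# backward through one conv layer; returns list(dW, db, dM)
.convBackward <- function(dOut, cache, W, k) {
  dA <- dOut * (cache$A > 0)
  list(dW = crossprod(cache$Z, dA),
       db = colSums(dA),
       dM = .convWindowsBackward(dA %*% t(W), k, cache$in_rows,
                                 cache$in_cols))
}

# column-wise max pooling with argmax cache
.maxPool <- function(H) {
  am <- max.col(t(H), ties.method = "first")
  list(out = H[cbind(am, seq_len(ncol(H)))], argmax = am)
}

.maxPoolBackward <- function(dg, argmax, n_rows) {
  dH <- matrix(0, n_rows, length(dg))
  dH[cbind(argmax, seq_along(dg))] <- dg
  dH
}

# Adam state and update
.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
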
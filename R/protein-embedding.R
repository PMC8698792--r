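# Amino-acid tokenization and GloVe-style embedding pretraining.
#
# Each amino acid is one "word". The vocabulary is the 20 standard residues
# plus "X" for any unknown letter; index 0 is reserved for padding. The
# co-occurrence matrix counts token pairs within a sliding window, weighted
# by 1/distance, symmetric, never across sequence-record boundaries.

.AA_TOKENS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Amino-acid vocabulary
#'
#' The fixed token set: the 20 standard amino-acid letters (alphabetical) and
#' "X" for unknown residues. Index 0 is the padding symbol; tokens are
#' indexed 1..21 in the order returned here.
#'
#' @return named integer vector mapping token to index (PAD excluded).
#' @examples
#' aminoAcidVocabulary()["M"]
#' @export
aminoAcidVocabulary <- function() {
  stats::setNames(seq_along(.AA_TOKENS), .AA_TOKENS)
}

# integer token indices of one sequence (unknown letters -> X)
.tokenize <- function(sequence) {
  letters <- strsplit(toupper(sequence), "")[[1]]
  idx <- match(letters, .AA_TOKENS)
  idx[is.na(idx)] <- match("X", .AA_TOKENS)
  idx
}

#' Token co-occurrence matrix of a protein corpus
#'
#' For every ordered token pair at distance `d <= window_size` within one
#' sequence, `1/d` is added to both symmetric cells. Sequences do not
#' co-occur across record boundaries.
#'
#' @param corpus character vector of protein sequences (or an
#'   `AAStringSet`).
#' @param window_size context window size (default 5).
#' @return symmetric non-negative 21 x 21 matrix over the vocabulary tokens.
#' @examples
#' buildCooccurrence(c("AC"), window_size = 1)["A", "C"]  # 1
#' @export
buildCooccurrence <- function(corpus, window_size = 5) {
  if (methods::is(corpus, "XStringSet")) corpus <- as.character(corpus)
  stopifnot(is.character(corpus))
  if (length(corpus) == 0) stop("corpus must be non-empty")
  if (window_size < 1) stop("window_size must be >= 1")
  V <- length(.AA_TOKENS)
  M <- matrix(0, V, V, dimnames = list(.AA_TOKENS, .AA_TOKENS))
  for (s in corpus) {
    idx <- .tokenize(s)
    n <- length(idx)
    for (d in seq_len(min(window_size, n - 1))) {
      a <- idx[seq_len(n - d)]
      b <- idx[seq(1 + d, n)]
      w <- 1 / d
      # aggregate duplicated index pairs before the matrix update
      tab <- table(paste(a, b))
      ij <- do.call(rbind, lapply(strsplit(names(tab), " "), as.integer))
      M[ij] <- M[ij] + w * as.numeric(tab)
      M[ij[, c(2, 1), drop = FALSE]] <-
        M[ij[, c(2, 1), drop = FALSE]] + w * as.numeric(tab)
    }
  }
  M
}

#' Train GloVe-style embeddings from a co-occurrence matrix
#'
#' Minimizes the weighted least-squares objective
#' `sum f(x_ij) (w_i . u_j + b_i + c_j - log x_ij)^2` over the non-zero
#' cells, with `f(x) = min(1, (x / x_max)^alpha)`, by AdaGrad stochastic
#' updates. The returned embedding is the sum of word and context vectors;
#' a leading all-zero row represents the padding index 0.
#'
#' @param cooc symmetric co-occurrence matrix from [buildCooccurrence()].
#' @param d embedding dimensionality (default 128).
#' @param epochs passes over the non-zero cells (default 25).
#' @param seed RNG seed.
#' @param x_max,alpha weighting-function parameters (GloVe defaults).
#' @param learning_rate initial AdaGrad step size.
#' @return numeric matrix with `nrow(cooc) + 1` rows (PAD first, all zero)
#'   and `d` columns; rownames are `c("<PAD>", rownames(cooc))`. The final
#'   objective value is attached as attribute `"loss"`.
#' @export
trainGlove <- function(cooc, d = 128, epochs = 25, seed = 1,
                       x_max = 100, alpha = 0.75, learning_rate = 0.05) {
  stopifnot(is.matrix(cooc), nrow(cooc) == ncol(cooc), d >= 1)
  V <- nrow(cooc)
  nz <- which(cooc > 0, arr.ind = TRUE)
  set.seed(seed)
  W <- matrix(stats::runif(V * d, -0.5, 0.5) / d, V, d)
  U <- matrix(stats::runif(V * d, -0.5, 0.5) / d, V, d)
  b <- stats::runif(V, -0.5, 0.5) / d
  cb <- stats::runif(V, -0.5, 0.5) / d
  gW <- matrix(1, V, d); gU <- matrix(1, V, d)
  gb <- rep(1, V); gcb <- rep(1, V)

  if (nrow(nz) > 0) {
    x <- cooc[nz]
    fx <- pmin(1, (x / x_max)^alpha)
    lx <- log(x)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(nz))
      for (k in ord) {
        i <- nz[k, 1]; j <- nz[k, 2]
        diff <- sum(W[i, ] * U[j, ]) + b[i] + cb[j] - lx[k]
        g <- fx[k] * diff
        dW <- g * U[j, ]; dU <- g * W[i, ]
        W[i, ] <- W[i, ] - learning_rate * dW / sqrt(gW[i, ])
        U[j, ] <- U[j, ] - learning_rate * dU / sqrt(gU[j, ])
        gW[i, ] <- gW[i, ] + dW^2
        gU[j, ] <- gU[j, ] + dU^2
        b[i] <- b[i] - learning_rate * g / sqrt(gb[i])
        cb[j] <- cb[j] - learning_rate * g / sqrt(gcb[j])
        gb[i] <- gb[i] + g^2
        gcb[j] <- gcb[j] + g^2
      }
    }
  }
  E <- rbind(0, W + U)
  rownames(E) <- c("<PAD>", rownames(cooc))
  attr(E, "loss") <- gloveObjective(cooc, E, x_max = x_max, alpha = alpha,
                                    b = b, cb = cb, W = W, U = U)
  E
}

#' GloVe objective value
#'
#' Evaluates the weighted least-squares objective on the non-zero cells.
#' With `W`/`U`/`b`/`cb` given, uses those factors; otherwise treats `E`
#' (PAD row dropped) as both word and context matrix with zero biases, which
#' is only meaningful for relative comparisons.
#'
#' @param cooc co-occurrence matrix.
#' @param E embedding matrix with PAD row (used when factors are absent).
#' @param x_max,alpha weighting parameters.
#' @param W,U,b,cb optional trained factors.
#' @return scalar objective value.
#' @export
gloveObjective <- function(cooc, E = NULL, x_max = 100, alpha = 0.75,
                           W = NULL, U = NULL, b = NULL, cb = NULL) {
  nz <- which(cooc > 0, arr.ind = TRUE)
  if (nrow(nz) == 0) return(0)
  x <- cooc[nz]
  fx <- pmin(1, (x / x_max)^alpha)
  if (is.null(W)) {
    Wm <- E[-1, , drop = FALSE] / 2
    Um <- Wm
    b <- cb <- rep(0, nrow(Wm))
  } else {
    Wm <- W; Um <- U
  }
  pred <- rowSums(Wm[nz[, 1], , drop = FALSE] * Um[nz[, 2], , drop = FALSE]) +
    b[nz[, 1]] + cb[nz[, 2]]
  sum(fx * (pred - log(x))^2)
}

#' Encode a protein sequence as a fixed-length index vector
#'
#' Letters map to vocabulary indices (unknown letters to "X"); the sequence
#' is truncated at `L` and right-padded with the padding index 0 to exactly
#' `L` entries.
#'
#' @param sequence amino-acid sequence (single string).
#' @param L fixed encoded length (default 1000).
#' @return integer vector of length `L` with attribute `original_length`.
#' @examples
#' sum(encodeProtein("MKV") != 0)  # 3
#' @export
encodeProtein <- function(sequence, L = 1000) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  idx <- .tokenize(sequence)
  orig <- length(idx)
  out <- integer(L)
  keep <- min(orig, L)
  out[seq_len(keep)] <- idx[seq_len(keep)]
  attr(out, "original_length") <- orig
  out
}

#' Write an embedding matrix as TSV
#'
#' One line per token: token, TAB, d tab-separated values. The PAD row is
#' included as token `<PAD>`.
#'
#' @param embedding matrix from [trainGlove()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeEmbedding <- function(embedding, path) {
  stopifnot(is.matrix(embedding), !is.null(rownames(embedding)))
  lines <- vapply(seq_len(nrow(embedding)), function(i)
    paste(c(rownames(embedding)[i],
            formatC(embedding[i, ], format = "g", digits = 17)),
          collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an embedding matrix from TSV
#'
#' @param path TSV written by [writeEmbedding()].
#' @return numeric matrix with token rownames.
#' @export
readEmbedding <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  E <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  rownames(E) <- vapply(parts, `[[`, "", 1)
  E
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
readProteinFasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(seqs), names(seqs))
}
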
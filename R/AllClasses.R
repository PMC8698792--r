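#' @import methods
NULL

#' Molecule: a sanitized heavy-atom molecular graph
#'
#' Container for one parsed molecule. Atoms are heavy (non-hydrogen) atoms in
#' the toolkit's parse order; hydrogens are folded into per-atom counts.
#' Atom indices are 1-based and stable for the lifetime of the object.
#'
#' @slot atoms data.frame with one row per heavy atom and columns
#'   `symbol` (element), `charge` (formal charge), `aromatic` (logical),
#'   `in_ring` (logical), `degree` (heavy-atom degree), `total_h`
#'   (explicit + implicit hydrogens), `implicit_h`, `valence`
#'   (total valence = bond orders + hydrogens).
#' @slot bonds integer matrix with columns `a`, `b`, `order`; each row one
#'   bond between two distinct heavy atoms.
#' @slot rings list of integer vectors, the simple rings (smallest ring
#'   through each ring bond, deduplicated).
#' @slot smiles the source SMILES string.
#' @slot sdf the underlying `ChemmineR::SDF` object (heavy atoms only),
#'   kept for fragment extraction.
#'
#' @seealso [parseSmiles()]
#' @export
setClass("Molecule",
  representation(
    atoms  = "data.frame",
    bonds  = "matrix",
    rings  = "list",
    smiles = "character",
    sdf    = "ANY"
  )
)

setValidity("Molecule", function(object) {
  a <- object@atoms
  b <- object@bonds
  msgs <- character()
  need <- c("symbol", "charge", "aromatic", "in_ring", "degree",
            "total_h", "implicit_h", "valence")
  if (!all(need %in% names(a)))
    msgs <- c(msgs, "atoms is missing required columns")
  if (nrow(b) > 0) {
    if (any(b[, "a"] == b[, "b"]))
      msgs <- c(msgs, "bond joining an atom to itself")
    if (any(b[, c("a", "b")] < 1L) || any(b[, c("a", "b")] > nrow(a)))
      msgs <- c(msgs, "bond references an invalid atom index")
  }
  if (nrow(a) > 0 &&
      (any(a$total_h < 0) || any(a$implicit_h < 0) || any(a$valence < 0)))
    msgs <- c(msgs, "hydrogen counts and valences must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' AtomGraph: atom-level graph of one molecule
#'
#' Nodes are heavy atoms, edges are bonds. Node features are the
#' 101-dimensional one-hot atom descriptors (see [atomFeatureVector()]).
#'
#' @slot adjacency symmetric binary matrix, zero diagonal.
#' @slot features binary matrix, one row per atom, 101 columns.
#' @slot smiles source SMILES.
#' @export
setClass("AtomGraph",
  representation(adjacency = "matrix", features = "matrix",
                 smiles = "character")
)

setValidity("AtomGraph", function(object) {
  A <- object@adjacency
  X <- object@features
  msgs <- character()
  if (nrow(A) != ncol(A)) msgs <- c(msgs, "adjacency must be square")
  if (!isTRUE(all.equal(A, t(A)))) msgs <- c(msgs, "adjacency must be symmetric")
  if (any(diag(A) != 0)) msgs <- c(msgs, "adjacency must have zero diagonal")
  if (nrow(X) != nrow(A)) msgs <- c(msgs, "one feature row per atom required")
  if (ncol(X) != 101L) msgs <- c(msgs, "atom feature width must be 101")
  if (length(msgs)) msgs else TRUE
})

#' SubstructureGraph: substructure-level graph of one molecule
#'
#' Nodes are segmented substructures (rings merged at >= 3 shared atoms,
#' non-ring bonds, or a degenerate single atom); two nodes are adjacent iff
#' their atom sets intersect. Node features are the 35-dimensional
#' descriptors (see [substructureFeatureVector()]).
#'
#' @slot adjacency symmetric binary matrix, zero diagonal.
#' @slot features binary matrix, one row per substructure, 35 columns.
#' @slot membership list mapping substructure index to its atom indices.
#' @slot kinds character vector: "ring", "bond" or "atom" per node.
#' @slot smiles source SMILES.
#' @export
setClass("SubstructureGraph",
  representation(adjacency = "matrix", features = "matrix",
                 membership = "list", kinds = "character",
                 smiles = "character")
)

setValidity("SubstructureGraph", function(object) {
  A <- object@adjacency
  X <- object@features
  msgs <- character()
  if (nrow(A) != ncol(A)) msgs <- c(msgs, "adjacency must be square")
  if (!isTRUE(all.equal(A, t(A)))) msgs <- c(msgs, "adjacency must be symmetric")
  if (any(diag(A) != 0)) msgs <- c(msgs, "adjacency must have zero diagonal")
  if (ncol(X) != 35L) msgs <- c(msgs, "substructure feature width must be 35")
  if (length(object@membership) != nrow(A))
    msgs <- c(msgs, "one membership set per node required")
  if (length(msgs)) msgs else TRUE
})

#' SubstructureVocabulary: ordered set of canonical substructure keys
#'
#' Keys are canonical SMILES of extracted fragments, in first-seen order.
#' Serialized as TSV with 0-based contiguous ids.
#'
#' @slot keys character vector of unique canonical fragment SMILES.
#' @seealso [buildVocabulary()], [writeVocabulary()]
#' @export
setClass("SubstructureVocabulary",
  representation(keys = "character")
)

setValidity("SubstructureVocabulary", function(object) {
  if (anyDuplicated(object@keys)) "vocabulary keys must be unique" else TRUE
})

#' DTAModel: trained affinity model state
#'
#' Holds the model configuration, all parameter tensors (current and
#' best-validation), the per-epoch loss traces and the training seed.
#'
#' @slot config named list, see [modelConfig()].
#' @slot params named list of parameter matrices/vectors (final epoch).
#' @slot best_params parameters at the epoch with lowest validation MSE
#'   (equal to `params` when no validation split was used).
#' @slot history data.frame with columns epoch, train_mse and (optionally)
#'   val_mse.
#' @slot seed integer RNG seed used for training.
#' @export
setClass("DTAModel",
  representation(config = "list", params = "list", best_params = "list",
                 history = "data.frame", seed = "integer")
)

setValidity("DTAModel", function(object) {
  h <- object@history
  if (nrow(h) > 0 && any(!is.finite(h$train_mse)))
    "loss trace contains non-finite values" else TRUE
})

# ---- show methods ----

setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule: %d heavy atoms, %d bonds, %d simple rings\n",
              nrow(object@atoms), nrow(object@bonds), length(object@rings)))
  cat("  SMILES:", object@smiles, "\n")
})

setMethod("show", "AtomGraph", function(object) {
  cat(sprintf("AtomGraph: %d nodes, %d edges, %d features per node\n",
              nrow(object@adjacency), sum(object@adjacency) / 2,
              ncol(object@features)))
})

setMethod("show", "SubstructureGraph", function(object) {
  cat(sprintf(
    "SubstructureGraph: %d nodes (%s), %d edges, %d features per node\n",
    nrow(object@adjacency),
    paste(sprintf("%d %s", table(object@kinds), names(table(object@kinds))),
          collapse = ", "),
    sum(object@adjacency) / 2, ncol(object@features)))
})

setMethod("show", "SubstructureVocabulary", function(object) {
  cat(sprintf("SubstructureVocabulary: %d entries\n", length(object@keys)))
  n <- min(5L, length(object@keys))
  if (n > 0)
    cat(paste(sprintf("  %d\t%s", seq_len(n) - 1L, object@keys[seq_len(n)]),
              collapse = "\n"), if (length(object@keys) > n) "\n  ..." else "",
        "\n", sep = "")
})

setMethod("show", "DTAModel", function(object) {
  cat("DTAModel\n")
  cat(sprintf("  branch output: %d, fusion hidden: %s\n",
              object@config$branch_dim,
              paste(object@config$fc_hidden, collapse = ", ")))
  if (nrow(object@history) > 0)
    cat(sprintf("  trained %d epochs, final train MSE %.4f\n",
                nrow(object@history),
                object@history$train_mse[nrow(object@history)]))
})

# ---- accessors ----

#' Number of nodes of a graph object
#' @param x an AtomGraph, SubstructureGraph or Molecule.
#' @return integer node (atom) count.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname nNodes
#' @export
setMethod("nNodes", "AtomGraph", function(x) nrow(x@adjacency))

#' @rdname nNodes
#' @export
setMethod("nNodes", "SubstructureGraph", function(x) nrow(x@adjacency))

#' @rdname nNodes
#' @export
setMethod("nNodes", "Molecule", function(x) nrow(x@atoms))

#' Adjacency matrix of a graph object
#' @param x an AtomGraph or SubstructureGraph.
#' @return symmetric binary matrix with zero diagonal.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname adjacency
#' @export
setMethod("adjacency", "AtomGraph", function(x) x@adjacency)

#' @rdname adjacency
#' @export
setMethod("adjacency", "SubstructureGraph", function(x) x@adjacency)

#' Node feature matrix of a graph object
#' @param x an AtomGraph or SubstructureGraph.
#' @return binary matrix, one row per node.
#' @export
setGeneric("nodeFeatures", function(x) standardGeneric("nodeFeatures"))

#' @rdname nodeFeatures
#' @export
setMethod("nodeFeatures", "AtomGraph", function(x) x@features)

#' @rdname nodeFeatures
#' @export
setMethod("nodeFeatures", "SubstructureGraph", function(x) x@features)

#' Atom table of a Molecule
#' @param x a Molecule.
#' @return the per-atom data.frame.
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname atomTable
#' @export
setMethod("atomTable", "Molecule", function(x) x@atoms)

#' Bond table of a Molecule
#' @param x a Molecule.
#' @return integer matrix with columns a, b, order.
#' @export
setGeneric("bondTable", function(x) standardGeneric("bondTable"))

#' @rdname bondTable
#' @export
setMethod("bondTable", "Molecule", function(x) x@bonds)

#' Vocabulary keys
#' @param x a SubstructureVocabulary.
#' @return character vector of canonical fragment SMILES, id order.
#' @export
setGeneric("vocabularyKeys", function(x) standardGeneric("vocabularyKeys"))

#' @rdname vocabularyKeys
#' @export
setMethod("vocabularyKeys", "SubstructureVocabulary", function(x) x@keys)

#' Substructure membership sets
#' @param x a SubstructureGraph.
#' @return list of integer atom-index vectors, one per node.
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname membership
#' @export
setMethod("membership", "SubstructureGraph", function(x) x@membership)

#' Training history of a model
#' @param x a DTAModel.
#' @return data.frame with per-epoch loss traces.
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @rdname trainingHistory
#' @export
setMethod("trainingHistory", "DTAModel", function(x) x@history)

#' Model configuration
#' @param x a DTAModel.
#' @return the named configuration list.
#' @export
setGeneric("modelConfigOf", function(x) standardGeneric("modelConfigOf"))

#' @rdname modelConfigOf
#' @export
setMethod("modelConfigOf", "DTAModel", function(x) x@config)
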
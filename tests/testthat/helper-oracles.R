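# Independent brute-force oracles and shared tiny fixtures for the suite.

# small molecules (<= 8 heavy atoms) exercising chains, rings, fused rings,
# bridged rings, heteroatoms and branching
oracle_molecules <- c(
  "CC", "CCO", "CC(C)C", "c1ccccc1", "C1CC1", "C1CC1CC", "c1ccoc1",
  "C1CC2CCC1C2", "C1CC1C1CC1", "N1CC1O", "C1CCC1C(=O)O", "CC#N"
)

# --- segmentation oracle: enumerate all simple cycles by DFS, then apply
# the substructure definition directly ---

# all simple cycles as ordered vertex paths (each set once)
oracle_all_cycles <- function(n, bonds) {
  adj <- lapply(seq_len(n), function(i)
    sort(unique(c(bonds[bonds[, "a"] == i, "b"],
                  bonds[bonds[, "b"] == i, "a"]))))
  cycles <- list()
  seen <- character(0)
  dfs <- function(start, v, path) {
    for (w in adj[[v]]) {
      if (w == start && length(path) >= 3) {
        key <- paste(sort(path), collapse = ",")
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          cycles[[length(cycles) + 1L]] <<- path
        }
      } else if (w > start && !(w %in% path)) {
        dfs(start, w, c(path, w))
      }
    }
  }
  for (s in seq_len(n)) dfs(s, s, s)
  cycles
}

cycle_edges <- function(path) {
  nxt <- c(path[-1], path[1])
  paste(pmin(path, nxt), pmax(path, nxt), sep = "-")
}

# substructure atom sets + kinds straight from the definition
oracle_segmentation <- function(mol) {
  bonds <- bondTable(mol)
  n <- nNodes(mol)
  cycles <- oracle_all_cycles(n, bonds)

  # smallest cycle length through every edge
  edge_min <- new.env(parent = emptyenv())
  for (cyc in cycles)
    for (e in cycle_edges(cyc)) {
      old <- if (exists(e, envir = edge_min)) get(e, envir = edge_min) else Inf
      assign(e, min(old, length(cyc)), envir = edge_min)
    }
  # simple rings: cycles that realize the minimum for some of their edges
  rings <- Filter(function(cyc)
    any(vapply(cycle_edges(cyc), function(e)
      get(e, envir = edge_min) == length(cyc), logical(1))), cycles)
  ring_edge_keys <- unique(unlist(lapply(rings, cycle_edges)))

  subs <- list()
  if (nrow(bonds) > 0)
    for (r in seq_len(nrow(bonds))) {
      e <- paste(min(bonds[r, 1:2]), max(bonds[r, 1:2]), sep = "-")
      if (!(e %in% ring_edge_keys))
        subs[[length(subs) + 1L]] <-
          list(kind = "bond", atoms = sort(unname(bonds[r, 1:2])))
    }
  sets <- lapply(rings, function(cyc) sort(unique(cyc)))
  repeat {
    done <- TRUE
    for (i in seq_along(sets)) {
      if (!done) break
      for (j in seq_along(sets)) {
        if (j <= i) next
        if (length(intersect(sets[[i]], sets[[j]])) >= 3) {
          sets[[i]] <- sort(union(sets[[i]], sets[[j]]))
          sets[[j]] <- NULL
          done <- FALSE
          break
        }
      }
    }
    if (done) break
  }
  sets <- sets[!duplicated(vapply(sets, paste, "", collapse = ","))]
  for (s in sets)
    subs[[length(subs) + 1L]] <- list(kind = "ring", atoms = s)
  covered <- if (length(subs)) unique(unlist(lapply(subs, `[[`, "atoms")))
             else integer(0)
  for (a in setdiff(seq_len(n), covered))
    subs[[length(subs) + 1L]] <- list(kind = "atom", atoms = a)
  subs
}

# canonical string form of a segmentation for set comparison
segmentation_signature <- function(subs) {
  sort(vapply(subs, function(s)
    paste(s$kind, paste(s$atoms, collapse = ","), sep = ":"), ""))
}

# --- per-node GCN message-passing oracle ---
oracle_gcn_forward <- function(H, A_norm, W, relu = TRUE) {
  HW <- H %*% W
  out <- matrix(0, nrow(H), ncol(W))
  for (i in seq_len(nrow(H)))
    for (j in seq_len(nrow(H)))
      out[i, ] <- out[i, ] + A_norm[i, j] * HW[j, ]
  if (relu) pmax(out, 0) else out
}

# --- exhaustive double-loop concordance index oracle ---
oracle_ci <- function(y_true, y_pred) {
  num <- 0
  Z <- 0
  for (i in seq_along(y_true))
    for (j in seq_along(y_true)) {
      if (y_true[i] > y_true[j]) {
        Z <- Z + 1
        d <- y_pred[i] - y_pred[j]
        num <- num + if (d > 0) 1 else if (d < 0) 0 else 0.5
      }
    }
  num / Z
}

# reduced-width configuration for desk-scale training tests
tiny_config <- function(epochs = 200L, batch_size = 10L,
                        learning_rate = 0.01, dropout = 0, seed = 11L) {
  modelConfig(batch_size = batch_size, learning_rate = learning_rate,
              epochs = epochs, dropout = dropout,
              embedding_dim = 8, protein_length = 300,
              conv_filters = c(8, 8, 8), conv_kernels = c(8, 8, 3),
              protein_fc_hidden = 32, branch_dim = 16,
              gcn_dims_atom = c(16, 16, 32), gcn_dims_sub = c(16, 16, 32),
              graph_fc_hidden = 32, attention_dk = 8, fc_hidden = c(64, 32),
              seed = seed)
}
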
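# Ring perception on the heavy-atom bond graph.
#
# A bond is a ring bond iff its endpoints stay connected after the bond is
# removed; the simple rings are the smallest ring through each ring bond
# (breadth-first shortest alternate path), deduplicated. On drug-scale
# molecules this reproduces the symmetrized smallest set of smallest rings.

# adjacency list (neighbours in ascending order, deterministic)
.adjList <- function(n_atoms, bonds) {
  adj <- vector("list", n_atoms)
  for (i in seq_len(n_atoms)) adj[[i]] <- integer(0)
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      a <- bonds[r, "a"]; b <- bonds[r, "b"]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    adj <- lapply(adj, function(v) sort(unique(v)))
  }
  adj
}

# BFS shortest path from u to v avoiding the direct edge u-v;
# returns ordered vertex path (u ... v) or NULL.
.shortestAlternatePath <- function(adj, u, v) {
  n <- length(adj)
  parent <- rep(NA_integer_, n)
  seen <- logical(n)
  seen[u] <- TRUE
  queue <- u
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    for (y in adj[[x]]) {
      if (x == u && y == v) next        # skip the direct edge
      if (!seen[y]) {
        seen[y] <- TRUE
        parent[y] <- x
        if (y == v) {
          path <- y
          while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
          return(path)
        }
        queue <- c(queue, y)
      }
    }
  }
  NULL
}

# internal: list of ordered cycles (integer vectors), deduplicated by atom set
.ringsFromBonds <- function(n_atoms, bonds) {
  if (nrow(bonds) == 0L) return(list())
  adj <- .adjList(n_atoms, bonds)
  rings <- list()
  seen_sets <- character(0)
  for (r in seq_len(nrow(bonds))) {
    u <- bonds[r, "a"]; v <- bonds[r, "b"]
    path <- .shortestAlternatePath(adj, u, v)
    if (is.null(path)) next
    key <- paste(sort(path), collapse = ",")
    if (!(key %in% seen_sets)) {
      seen_sets <- c(seen_sets, key)
      rings[[length(rings) + 1L]] <- as.integer(path)
    }
  }
  rings
}

#' Simple rings of a molecule
#'
#' Returns the simple rings of the heavy-atom graph: for every bond lying on
#' a cycle, the smallest cycle through that bond, deduplicated. Each ring is
#' an ordered vector of 1-based atom indices.
#'
#' @param molecule a [Molecule-class].
#' @return list of integer vectors; empty list for acyclic molecules.
#' @examples
#' findSimpleRings(parseSmiles("c1ccccc1"))
#' @export
findSimpleRings <- function(molecule) {
  stopifnot(is(molecule, "Molecule"))
  molecule@rings
}

# edges (sorted integer pairs "a-b") belonging to some simple ring
.ringEdgeKeys <- function(rings) {
  keys <- character(0)
  for (cyc in rings) {
    m <- length(cyc)
    nxt <- c(cyc[-1], cyc[1])
    keys <- c(keys, paste(pmin(cyc, nxt), pmax(cyc, nxt), sep = "-"))
  }
  unique(keys)
}
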
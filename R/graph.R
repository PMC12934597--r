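# Anonymous (label-free) graph machinery: the topological skeletons that the
# analog-search index is built over, their canonical keys, smallest set of
# smallest rings, and single-edit neighborhoods.
#
# Graph representation: list(n = <int>, edges = <m x 2 integer matrix>),
# rows sorted, each row (a, b) with a < b, vertices 1..n, simple undirected.

anon_graph <- function(n, edges) {
  n <- as.integer(n)
  if (length(edges)) {
    e <- matrix(as.integer(edges), ncol = 2)
    sw <- e[, 1] > e[, 2]
    e[sw, ] <- e[sw, 2:1, drop = FALSE]
    e <- unique(e[order(e[, 1], e[, 2]), , drop = FALSE])
    if (any(e[, 1] == e[, 2])) {
      abort_mgvs("self-loop in anonymous graph", "mgvs_graph_error")
    }
    if (any(e < 1L) || any(e > n)) {
      abort_mgvs("edge endpoint out of range", "mgvs_graph_error")
    }
  } else {
    e <- matrix(integer(0), ncol = 2)
  }
  structure(list(n = n, edges = e), class = "mgvs_anon_graph")
}

#' Strip a molecule to its anonymous heavy-atom skeleton
#'
#' Removes every atom and bond label (element, charge, aromaticity, bond
#' order), leaving only heavy-atom connectivity. Isomorphic skeletons are the
#' unit of retrieval for the graph-edit-distance index: benzene and
#' cyclohexane both map to the plain 6-cycle.
#'
#' @param mol a `mgvs_mol`.
#' @return An anonymous graph (`mgvs_anon_graph`).
#' @export
anonymize <- function(mol) {
  stopifnot(inherits(mol, "mgvs_mol"))
  anon_graph(nrow(mol$atoms), cbind(mol$bonds$a1, mol$bonds$a2))
}

#' @export
print.mgvs_anon_graph <- function(x, ...) {
  cat(sprintf("<anonymous graph: %d nodes, %d edges>\n", x$n, nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(g) {
  igraph::make_graph(t(g$edges), n = g$n, directed = FALSE)
}

graph_is_connected <- function(g) {
  if (g$n <= 1L) return(TRUE)
  igraph::is_connected(as_igraph(g))
}

#' Canonical key of an anonymous graph
#'
#' Two graphs receive the same key exactly when they are isomorphic. Keys are
#' produced by canonical vertex labeling (BLISS, via igraph) followed by a
#' stable serialization of the relabeled edge list, so they are reproducible
#' across runs and platforms and can be used as dictionary keys.
#'
#' @param g an `mgvs_anon_graph` (must be connected).
#' @return Character key.
#' @export
canonical_key <- function(g) {
  stopifnot(inherits(g, "mgvs_anon_graph"))
  if (!graph_is_connected(g)) {
    abort_mgvs("canonical_key requires a connected graph (multi-fragment molecules are rejected upstream)",
               "mgvs_graph_error")
  }
  if (g$n == 1L) return("1|")
  p <- igraph::canonical_permutation(as_igraph(g))$labeling
  e <- cbind(p[g$edges[, 1]], p[g$edges[, 2]])
  sw <- e[, 1] > e[, 2]
  e[sw, ] <- e[sw, 2:1, drop = FALSE]
  o <- order(e[, 1], e[, 2])
  paste0(g$n, "|", paste(e[o, 1], e[o, 2], sep = ".", collapse = ","))
}

# Rebuild a graph from its canonical key.
graph_from_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)[[1]]
  n <- as.integer(parts[[1]])
  if (length(parts) < 2L || !nzchar(parts[[2]])) return(anon_graph(n, NULL))
  pairs <- strsplit(strsplit(parts[[2]], ",", fixed = TRUE)[[1]], ".", fixed = TRUE)
  e <- matrix(as.integer(unlist(pairs)), ncol = 2, byrow = TRUE)
  anon_graph(n, e)
}

# All graphs one edit away under the connectivity-preserving edit set:
#   add a terminal node, delete a degree-1 node, add an edge between existing
#   non-adjacent nodes, delete a non-bridge edge.
edit_neighbors <- function(g) {
  n <- g$n
  e <- g$edges
  m <- nrow(e)
  out <- vector("list", n + m + n * (n - 1L) / 2L + m)
  k <- 0L
  deg <- tabulate(c(e[, 1], e[, 2]), nbins = n)
  for (v in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- anon_graph(n + 1L, rbind(e, c(v, n + 1L)))
  }
  if (n > 1L) {
    for (v in which(deg == 1L)) {
      keep <- !(e[, 1] == v | e[, 2] == v)
      e2 <- e[keep, , drop = FALSE]
      e2[e2 > v] <- e2[e2 > v] - 1L
      k <- k + 1L
      out[[k]] <- anon_graph(n - 1L, e2)
    }
  }
  if (n >= 2L) {
    adj <- matrix(FALSE, n, n)
    if (m) {
      adj[e] <- TRUE
      adj[e[, 2:1, drop = FALSE]] <- TRUE
    }
    nonadj <- which(upper.tri(adj) & !adj, arr.ind = TRUE)
    if (nrow(nonadj)) {
      for (i in seq_len(nrow(nonadj))) {
        k <- k + 1L
        out[[k]] <- anon_graph(n, rbind(e, nonadj[i, ]))
      }
    }
  }
  if (m >= 1L) {
    br <- as.integer(igraph::bridges(as_igraph(g)))
    for (i in setdiff(seq_len(m), br)) {
      k <- k + 1L
      out[[k]] <- anon_graph(n, e[-i, , drop = FALSE])
    }
  }
  out[seq_len(k)]
}

# ---- smallest set of smallest rings --------------------------------------
#
# Candidate rings are the shortest cycles through each edge; a greedy GF(2)
# elimination over edge-incidence vectors keeps m - n + 1 independent ones.
# Exact for the small molecular graphs this package handles.

sssr <- function(mol_or_graph) {
  g <- if (inherits(mol_or_graph, "mgvs_mol")) anonymize(mol_or_graph) else mol_or_graph
  n <- g$n
  e <- g$edges
  m <- nrow(e)
  ig <- as_igraph(g)
  ncomp <- igraph::components(ig)$no
  ncycles <- m - n + ncomp
  if (ncycles <= 0L) return(list())
  edge_id <- function(a, b) paste(pmin(a, b), pmax(a, b))
  eid <- edge_id(e[, 1], e[, 2])
  cand <- list()
  for (i in seq_len(m)) {
    ig2 <- igraph::delete_edges(ig, i)
    sp <- suppressWarnings(igraph::shortest_paths(ig2, from = e[i, 1], to = e[i, 2]))
    vp <- as.integer(sp$vpath[[1]])
    if (length(vp) < 2L) next # bridge: no cycle through this edge
    ring <- vp # vertex sequence from a to b; edge i closes it
    cand[[length(cand) + 1L]] <- ring
  }
  if (!length(cand)) return(list())
  # edge-incidence bit vectors
  ring_vec <- function(vs) {
    a <- vs
    b <- c(vs[-1], vs[1])
    ids <- edge_id(a, b)
    v <- logical(m)
    v[match(ids, eid)] <- TRUE
    v
  }
  sizes <- lengths(cand)
  o <- order(sizes)
  cand <- cand[o]
  vecs <- lapply(cand, ring_vec)
  basis <- vector("list", m) # indexed by pivot edge
  chosen <- list()
  for (i in seq_along(vecs)) {
    v <- vecs[[i]]
    repeat {
      p <- which(v)[1]
      if (is.na(p) || is.null(basis[[p]])) break
      v <- xor(v, basis[[p]])
    }
    if (any(v)) {
      basis[[which(v)[1]]] <- v
      chosen[[length(chosen) + 1L]] <- cand[[i]]
      if (length(chosen) == ncycles) break
    }
  }
  chosen
}

# Connected fused-ring systems: rings sharing >= 1 atom are in one system.
# Returns list of integer vectors of ring indices, plus the ring-adjacency
# edge list (pairs of rings sharing at least one atom).
fused_ring_systems <- function(rings) {
  nr <- length(rings)
  if (nr == 0L) return(list(systems = list(), adjacency = matrix(integer(0), ncol = 2)))
  adj <- matrix(integer(0), ncol = 2)
  if (nr >= 2L) {
    for (i in seq_len(nr - 1L)) {
      for (j in seq(i + 1L, nr)) {
        if (length(intersect(rings[[i]], rings[[j]])) >= 1L) {
          adj <- rbind(adj, c(i, j))
        }
      }
    }
  }
  rg <- igraph::make_graph(t(adj), n = nr, directed = FALSE)
  comp <- igraph::components(rg)$membership
  systems <- split(seq_len(nr), comp)
  list(systems = unname(systems), adjacency = adj)
}
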
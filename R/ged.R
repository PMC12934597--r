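# Graph-edit-distance search over anonymous molecular skeletons.
#
# The edit set is connectivity-preserving: add a terminal node, delete a
# degree-1 node, add an edge between existing nodes, delete a non-bridge
# edge. Label changes are free because the graphs are anonymous. The edit
# relation is symmetric, so shells around a graph double as both forward and
# backward search frontiers.
#
# Distances are computed by bidirectional level-wise search over canonical
# keys: shells are materialized lazily and memoized package-wide (they are
# content-addressed, so sharing across queries and libraries is sound). A
# distance is reported once the two expansions meet; expansion stops when the
# radii sum to the requested bound, which makes the result exact within that
# bound.

.ged_cache <- new.env(parent = emptyenv())
.ged_cache$graphs <- new.env(parent = emptyenv())     # key -> graph
.ged_cache$shells <- new.env(parent = emptyenv())     # key -> shell state env
.ged_cache$neighbors <- new.env(parent = emptyenv())  # key -> neighbor keys

#' Reset the memoized GED shell cache
#'
#' Frees the lazily materialized edit-lattice shells. Only useful to bound
#' memory in long sessions; results are unaffected.
#' @export
ged_cache_reset <- function() {
  .ged_cache$graphs <- new.env(parent = emptyenv())
  .ged_cache$shells <- new.env(parent = emptyenv())
  .ged_cache$neighbors <- new.env(parent = emptyenv())
  invisible(NULL)
}

# memoized canonical keys of the 1-edit neighborhood of a key
neighbor_keys <- function(key) {
  ks <- .ged_cache$neighbors[[key]]
  if (!is.null(ks)) return(ks)
  g <- .ged_cache$graphs[[key]]
  nbs <- edit_neighbors(g)
  ks <- character(length(nbs))
  for (i in seq_along(nbs)) {
    ki <- canonical_key(nbs[[i]])
    ks[[i]] <- ki
    if (is.null(.ged_cache$graphs[[ki]])) .ged_cache$graphs[[ki]] <- nbs[[i]]
  }
  ks <- unique(ks)
  .ged_cache$neighbors[[key]] <- ks
  ks
}

# count-based lower bound on the edit distance between two keys: node edits
# change node and edge counts together, edge edits change only edges
ged_lower_bound <- function(k1, k2) {
  p1 <- key_counts(k1)
  p2 <- key_counts(k2)
  dn <- p2[1] - p1[1]
  dm <- p2[2] - p1[2]
  if (dn == 0 || dm == 0 || sign(dn) == sign(dm)) {
    max(abs(dn), abs(dm))
  } else {
    abs(dn) + abs(dm)
  }
}

key_counts <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)[[1]]
  n <- as.integer(parts[[1]])
  m <- if (length(parts) < 2L || !nzchar(parts[[2]])) 0L else
    length(gregexpr(",", parts[[2]], fixed = TRUE)[[1]]) + 1L
  if (length(parts) >= 2L && !grepl(",", parts[[2]], fixed = TRUE) &&
      nzchar(parts[[2]])) m <- 1L
  c(n, m)
}

register_graph <- function(g, key = canonical_key(g)) {
  if (is.null(.ged_cache$graphs[[key]])) .ged_cache$graphs[[key]] <- g
  key
}

shell_state <- function(key) {
  st <- .ged_cache$shells[[key]]
  if (is.null(st)) {
    st <- new.env(parent = emptyenv())
    st$dist <- new.env(parent = emptyenv())
    st$dist[[key]] <- 0L
    st$levels <- list(key)
    st$radius <- 0L
    .ged_cache$shells[[key]] <- st
  }
  st
}

# grow the shell state of `key` by one level; returns the new frontier keys
expand_shell <- function(st) {
  frontier <- st$levels[[st$radius + 1L]]
  r <- st$radius + 1L
  newf <- character(0)
  for (k in frontier) {
    for (nk in neighbor_keys(k)) {
      if (is.null(st$dist[[nk]])) {
        st$dist[[nk]] <- r
        newf <- c(newf, nk)
      }
    }
  }
  st$levels[[r + 1L]] <- newf
  st$radius <- r
  newf
}

# exact distance between two canonical keys, NA if > maxd
ged_between_keys <- function(k1, k2, maxd) {
  if (k1 == k2) return(0L)
  if (maxd < 1L) return(NA_integer_)
  if (ged_lower_bound(k1, k2) > maxd) return(NA_integer_)
  s1 <- shell_state(k1)
  s2 <- shell_state(k2)
  best <- Inf
  meet <- function(sa, sb) {
    # best sum over sa's materialized keys found in sb's table
    b <- Inf
    for (r in seq_along(sa$levels)) {
      for (k in sa$levels[[r]]) {
        db <- sb$dist[[k]]
        if (!is.null(db)) b <- min(b, (r - 1L) + db)
      }
    }
    b
  }
  best <- min(meet(s1, s2), meet(s2, s1))
  repeat {
    if (best <= s1$radius + s2$radius) break
    if (s1$radius + s2$radius >= maxd) break
    # expand the cheaper side (smaller current frontier)
    sa <- if (length(s1$levels[[s1$radius + 1L]]) <=
              length(s2$levels[[s2$radius + 1L]])) s1 else s2
    sb <- if (identical(sa, s1)) s2 else s1
    newf <- expand_shell(sa)
    for (k in newf) {
      db <- sb$dist[[k]]
      if (!is.null(db)) best <- min(best, sa$radius + db)
    }
  }
  if (is.finite(best) && best <= maxd) as.integer(best) else NA_integer_
}

#' Exact graph edit distance between two anonymous graphs
#'
#' Minimum number of single edits (terminal node addition/deletion, edge
#' addition, connectivity-preserving edge deletion) transforming `g1` into a
#' graph isomorphic to `g2`. Exact within the search bound `max_d`; `NA` is
#' returned when the distance exceeds it.
#'
#' @param g1,g2 connected `mgvs_anon_graph` objects.
#' @param max_d non-negative search bound. Cost grows steeply with the bound:
#'   desk-scale use is bounded expansion around small molecules, not
#'   arbitrary-distance computation.
#' @return Integer distance, or `NA` if greater than `max_d`.
#' @export
exact_ged <- function(g1, g2, max_d) {
  stopifnot(inherits(g1, "mgvs_anon_graph"), inherits(g2, "mgvs_anon_graph"))
  if (!is.numeric(max_d) || length(max_d) != 1L || max_d < 0) {
    abort_mgvs("max_d must be a single non-negative number", "mgvs_argument_error")
  }
  k1 <- register_graph(g1)
  k2 <- register_graph(g2)
  ged_between_keys(k1, k2, as.integer(max_d))
}

# ---- library index --------------------------------------------------------

#' Build a graph-edit-distance index over a compound library
#'
#' Buckets the library by the canonical key of each member's anonymous
#' skeleton, the pre-indexing that makes topological search fast: all
#' compounds with isomorphic skeletons share one bucket, and query-time work
#' scales with distinct topologies, not library size. Lattice edges between
#' bucket keys at edit distance 1 are recorded at build time; deeper shells
#' of the edit lattice are materialized lazily during queries.
#'
#' @param library list of `mgvs_mol` (unique ids, connected molecules).
#' @param params list; `lattice = FALSE` skips the distance-1 lattice edges.
#' @return A `mgvs_ged_index`.
#' @export
build_index <- function(library, params = list()) {
  ids <- vapply(library, function(m) m$id, "")
  if (anyDuplicated(ids)) {
    abort_mgvs(sprintf("duplicate compound ids in library: %s",
                       paste(unique(ids[duplicated(ids)]), collapse = ", ")),
               "mgvs_input_error")
  }
  buckets <- list()
  mols <- stats::setNames(library, ids)
  for (m in library) {
    g <- anonymize(m)
    if (!graph_is_connected(g)) {
      abort_mgvs(sprintf("library compound '%s' is not connected", m$id),
                 "mgvs_input_error")
    }
    key <- register_graph(g)
    buckets[[key]] <- c(buckets[[key]], m$id)
  }
  lattice <- matrix(character(0), ncol = 2)
  if (!identical(params$lattice, FALSE) && length(buckets) > 1L) {
    keys <- names(buckets)
    keyset <- new.env(parent = emptyenv())
    for (k in keys) keyset[[k]] <- TRUE
    for (k in keys) {
      nbk <- neighbor_keys(k)
      hits <- nbk[vapply(nbk, function(x) !is.null(keyset[[x]]), TRUE)]
      for (h in hits) {
        if (k < h) lattice <- rbind(lattice, c(k, h))
      }
    }
  }
  structure(list(buckets = buckets, mols = mols, lattice = lattice,
                 meta = list(size = length(library),
                             n_buckets = length(buckets),
                             params = params)),
            class = "mgvs_ged_index")
}

#' @export
print.mgvs_ged_index <- function(x, ...) {
  cat(sprintf("<GED index: %d compounds in %d topology buckets, %d lattice edges>\n",
              x$meta$size, x$meta$n_buckets, nrow(x$lattice)))
  invisible(x)
}

#' Query a GED index for the closest library compounds
#'
#' Expands the edit lattice outward from the query skeleton, exhausting
#' closer shells before farther ones, and returns up to `max_hits` compounds
#' within `max_ged` edits. Hits are ordered by (GED, Daylight-style path
#' fingerprint distance, id); fingerprint distances against the query are
#' reported for every hit.
#'
#' @param index a `mgvs_ged_index`.
#' @param query a connected `mgvs_mol`.
#' @param max_ged maximum edit distance (default 12, the service-scale search
#'   radius; use small radii at desk scale).
#' @param max_hits maximum number of hits (default 1000).
#' @return data.frame with columns `query_id`, `hit_id`, `ged`,
#'   `daylight_dist`, `ecfp4_dist`, ordered as above.
#' @export
query_index <- function(index, query, max_ged = 12, max_hits = 1000) {
  stopifnot(inherits(index, "mgvs_ged_index"), inherits(query, "mgvs_mol"))
  qg <- anonymize(query)
  if (!graph_is_connected(qg)) {
    abort_mgvs(sprintf("query '%s' is not connected", query$id), "mgvs_input_error")
  }
  qkey <- register_graph(qg)
  keys <- names(index$buckets)
  empty <- data.frame(query_id = character(0), hit_id = character(0),
                      ged = integer(0), daylight_dist = numeric(0),
                      ecfp4_dist = numeric(0), stringsAsFactors = FALSE)
  if (!length(keys)) return(empty)
  dist <- vapply(keys, function(k) {
    d <- ged_between_keys(qkey, k, as.integer(max_ged))
    if (is.na(d)) NA_integer_ else d
  }, integer(1))
  found <- which(!is.na(dist))
  if (!length(found)) return(empty)
  qfp_path <- path_fingerprint(query)
  qfp_circ <- circular_fingerprint(query)
  rows <- list()
  for (i in found) {
    for (id in index$buckets[[keys[[i]]]]) {
      m <- index$mols[[id]]
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = query$id, hit_id = id, ged = dist[[i]],
        daylight_dist = tanimoto_distance(qfp_path, path_fingerprint(m)),
        ecfp4_dist = tanimoto_distance(qfp_circ, circular_fingerprint(m)),
        stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$ged, hits$daylight_dist, hits$hit_id), , drop = FALSE]
  rownames(hits) <- NULL
  utils::head(hits, max_hits)
}
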
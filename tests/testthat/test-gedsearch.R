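# Anonymous graphs, canonical keys, exact GED and the search index.

test_that("anonymize strips all labels down to the heavy-atom skeleton", {
  bz <- anonymize(fx_mol("c1ccccc1", "bz"))
  chx <- anonymize(fx_mol("C1CCCCC1", "chx"))
  expect_equal(bz$n, 6)
  expect_equal(nrow(bz$edges), 6)
  expect_identical(canonical_key(bz), canonical_key(chx))
  but <- anonymize(fx_mol("CCCC", "butane"))
  expect_identical(canonical_key(but), canonical_key(path_graph(4)))
})

test_that("canonical keys separate non-isomorphic graphs and are relabeling-invariant", {
  expect_false(canonical_key(path_graph(4)) ==
                 canonical_key(mgvs:::anon_graph(4, cbind(rep(1, 3), 2:4))))
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    g <- random_anon_graph(n, extra = 2L)
    perm <- sample(n)
    e2 <- cbind(perm[g$edges[, 1]], perm[g$edges[, 2]])
    g2 <- mgvs:::anon_graph(n, e2)
    expect_identical(canonical_key(g), canonical_key(g2))
    # oracle: igraph isomorphism agrees with key equality
    expect_true(igraph::is_isomorphic_to(mgvs:::as_igraph(g),
                                         mgvs:::as_igraph(g2)))
  }
  expect_error(canonical_key(mgvs:::anon_graph(4, cbind(1, 2))),
               class = "mgvs_graph_error")
})

test_that("exact_ged matches enumeration-level expectations", {
  c6 <- cycle_graph(6)
  expect_equal(exact_ged(c6, c6, 12), 0)
  expect_equal(exact_ged(path_graph(3), path_graph(4), 12), 1)
  # 6-cycle vs 6-path: non-isomorphic so > 0, and deleting one cycle edge is
  # a 1-edit witness; BFS must therefore report exactly 1
  expect_equal(exact_ged(c6, path_graph(6), 12), 1)
  expect_equal(exact_ged(path_graph(2), c6, 5), 5)
  expect_true(is.na(exact_ged(path_graph(2), c6, 4)))
  expect_error(exact_ged(c6, c6, -1), class = "mgvs_argument_error")
})

test_that("single-edit neighborhoods witness distance-1 pairs exactly", {
  g <- anonymize(fx_mol("c1ccccc1", "bz"))
  nb_keys <- unique(vapply(mgvs:::edit_neighbors(g), canonical_key, ""))
  # toluene skeleton is one terminal addition away
  tol <- anonymize(fx_mol("Cc1ccccc1", "tol"))
  expect_true(canonical_key(tol) %in% nb_keys)
  # 6-path is one (connectivity-preserving) edge deletion away
  expect_true(canonical_key(path_graph(6)) %in% nb_keys)
  # every neighbor is at exact_ged 1 (none can be 0: an edit changes n or m)
  for (k in sample(nb_keys, min(5, length(nb_keys)))) {
    expect_equal(exact_ged(g, mgvs:::graph_from_key(k), 2), 1)
  }
})

test_that("index building buckets by topology and links distance-1 keys", {
  lib <- list(fx_mol("c1ccccc1", "benzene"), fx_mol("C1CCCCC1", "cyclohexane"),
              fx_mol("c1ccncc1", "pyridine"))
  idx <- build_index(lib)
  expect_equal(idx$meta$n_buckets, 1)
  expect_equal(sort(idx$buckets[[1]]), c("benzene", "cyclohexane", "pyridine"))

  alkanes <- list(fx_mol("CC", "ethane"), fx_mol("CCC", "propane"),
                  fx_mol("CCCC", "butane"))
  idx2 <- build_index(alkanes)
  expect_equal(idx2$meta$n_buckets, 3)
  expect_equal(nrow(idx2$lattice), 2) # ethane-propane, propane-butane

  expect_equal(build_index(list())$meta$size, 0)
  expect_error(build_index(list(fx_mol("CC", "x"), fx_mol("CCC", "x"))),
               class = "mgvs_input_error")
})

test_that("query results carry exact GED values and respect the radius", {
  lib <- list(fx_mol("c1ccccc1", "benzene"), fx_mol("C1CCCCC1", "cyclohexane"),
              fx_mol("c1ccncc1", "pyridine"))
  idx <- build_index(lib)
  hits <- query_index(idx, fx_mol("c1ccccc1", "q"), max_ged = 2)
  expect_equal(nrow(hits), 3)
  expect_true(all(hits$ged == 0))
  expect_true(all(hits$daylight_dist >= 0 & hits$daylight_dist <= 1))

  h2 <- query_index(build_index(list(fx_mol("c1ccccc1", "benzene"))),
                    fx_mol("Cc1ccccc1", "toluene"), max_ged = 12)
  expect_equal(h2$ged, 1)

  h3 <- query_index(idx, fx_mol("CCCCCCCC", "octane"), max_ged = 0)
  expect_equal(nrow(h3), 0)
})

test_that("hit ordering is deterministic and truncation is monotone", {
  set.seed(21)
  lib <- make_library(c(a = "c1ccccc1", b = "CCCCCC"), edit_radius = 2,
                      n_members = 25, rng_seed = 77)
  idx <- build_index(lib$members)
  q <- fx_mol("Cc1ccccc1", "q")
  full <- query_index(idx, q, max_ged = 3, max_hits = 1000)
  expect_false(is.unsorted(full$ged))
  for (k in c(1, 3, 7)) {
    if (k <= nrow(full)) {
      part <- query_index(idx, q, max_ged = 3, max_hits = k)
      expect_identical(part, full[seq_len(k), ])
    }
  }
})

test_that("GED is a metric on sampled skeleton triples", {
  set.seed(5)
  graphs <- replicate(12, random_anon_graph(sample(4:8, 1)), simplify = FALSE)
  for (t in 1:40) {
    i <- sample(12, 3, replace = TRUE)
    d12 <- exact_ged(graphs[[i[1]]], graphs[[i[2]]], 8)
    d21 <- exact_ged(graphs[[i[2]]], graphs[[i[1]]], 8)
    expect_identical(d12, d21)
    d23 <- exact_ged(graphs[[i[2]]], graphs[[i[3]]], 8)
    d13 <- exact_ged(graphs[[i[1]]], graphs[[i[3]]], 8)
    if (!is.na(d12) && !is.na(d23) && !is.na(d13)) {
      expect_lte(d13, d12 + d23)
    }
    expect_equal(exact_ged(graphs[[i[1]]], graphs[[i[1]]], 8), 0)
  }
})
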
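# Geometric interaction detection and matching.

test_that("planted hydrogen bonds obey both distance and angle criteria", {
  ok <- plant_complex(list(list(kind = "hbond", distance = 3.4, angle = 160)))
  ints <- detect_interactions(ok$pose, ok$receptor)
  expect_equal(ints$kind, "hbond")
  expect_equal(ints$distance, 3.4, tolerance = 0.01)
  expect_equal(ints$angle, 160, tolerance = 1)

  too_far <- plant_complex(list(list(kind = "hbond", distance = 3.6, angle = 160)))
  expect_equal(nrow(detect_interactions(too_far$pose, too_far$receptor)), 0)

  bent <- plant_complex(list(list(kind = "hbond", distance = 3.4, angle = 100)))
  expect_equal(nrow(detect_interactions(bent$pose, bent$receptor)), 0)
})

test_that("each planted interaction kind is detected exactly once", {
  cases <- list(
    list(kind = "hydrophobic", distance = 3.7),
    list(kind = "salt_bridge", distance = 3.9),
    list(kind = "pi_stack", distance = 3.6, plane_angle = 0),
    list(kind = "pi_stack", distance = 5.4, plane_angle = 70),
    list(kind = "pi_cation", distance = 3.8))
  for (cs in cases) {
    pc <- plant_complex(list(cs))
    ints <- detect_interactions(pc$pose, pc$receptor)
    expect_equal(nrow(ints), 1, info = cs$kind)
    expect_equal(ints$kind, cs$kind)
    expect_equal(ints$distance, cs$distance, tolerance = 0.02)
  }
  # parallel vs perpendicular stacking subtypes
  par <- plant_complex(list(list(kind = "pi_stack", distance = 3.6,
                                 plane_angle = 0)))
  expect_equal(detect_interactions(par$pose, par$receptor)$subtype, "parallel")
  perp <- plant_complex(list(list(kind = "pi_stack", distance = 5.4,
                                  plane_angle = 70)))
  expect_equal(detect_interactions(perp$pose, perp$receptor)$subtype,
               "perpendicular")
})

test_that("multi-interaction complexes detect exactly the planted set", {
  pc <- plant_complex(list(list(kind = "salt_bridge", distance = 3.9),
                           list(kind = "pi_stack", distance = 3.6,
                                plane_angle = 0),
                           list(kind = "hbond", distance = 3.2, angle = 170)))
  ints <- detect_interactions(pc$pose, pc$receptor)
  expect_setequal(ints$kind, c("salt_bridge", "pi_stack", "hbond"))
  expect_equal(nrow(ints), 3)
})

test_that("a ligand pose without hydrogens is rejected up front", {
  pc <- plant_complex(list(list(kind = "hbond", distance = 3.2, angle = 160)))
  noh <- pc$pose
  keep <- noh$atoms$element != "H"
  remap <- cumsum(keep)
  noh$bonds <- noh$bonds[keep[noh$bonds$a1] & keep[noh$bonds$a2], ]
  noh$bonds$a1 <- remap[noh$bonds$a1]; noh$bonds$a2 <- remap[noh$bonds$a2]
  noh$atoms <- noh$atoms[keep, ]
  expect_error(detect_interactions(noh, pc$receptor),
               class = "mgvs_precondition_error")
})

test_that("matching distinguishes atom- from residue-level identity", {
  qi <- data.frame(kind = c("hbond", "hbond"),
                   lig_atoms = c("1", "2"),
                   prot_atoms = c("A:25:ASP:OD1", "A:48:GLY:O"),
                   residue = c("A:25:ASP", "A:48:GLY"),
                   stringsAsFactors = FALSE)
  hi <- data.frame(kind = "hbond", lig_atoms = "9",
                   prot_atoms = "A:25:ASP:OD2", residue = "A:25:ASP",
                   stringsAsFactors = FALSE)
  at <- match_interactions(qi, hi, level = "atom")
  expect_equal(at$shared, 0)
  expect_false(at$any_shared)
  rs <- match_interactions(qi, hi, level = "residue")
  expect_equal(rs$shared, 1)
  expect_true(rs$any_shared)
  expect_false(rs$all_shared)

  ident <- match_interactions(qi, qi, level = "atom")
  expect_true(ident$all_shared)
  empty <- match_interactions(qi, qi[0, ], level = "atom")
  expect_equal(empty$shared, 0)
  expect_false(empty$any_shared)
  expect_error(match_interactions(qi, hi, level = "bogus"))
})

test_that("scope restriction drops hydrophobics and never raises shared counts", {
  set.seed(31)
  for (i in 1:25) {
    q <- random_interactions(6)
    h <- random_interactions(6)
    for (lv in c("atom", "residue")) {
      full <- match_interactions(q, h, level = lv, scope = "all")
      spec <- match_interactions(q, h, level = lv, scope = "specific")
      expect_lte(spec$shared, full$shared)
      expect_false("hydrophobic" %in% spec$per_kind$kind)
    }
  }
})

test_that("proportion tables reproduce a hand-computed 2-query fixture", {
  mk <- function(kinds, atoms, res) data.frame(
    kind = kinds, lig_atoms = as.character(seq_along(kinds)),
    prot_atoms = atoms, residue = res, stringsAsFactors = FALSE)
  q1 <- mk("hbond", "A:1:SER:OG", "A:1:SER")
  q2 <- mk("hbond", "A:2:THR:OG1", "A:2:THR")
  h_match <- q1
  h_miss <- mk("hbond", "A:9:TYR:OH", "A:9:TYR")
  st <- shared_interaction_stats(list(
    list(query = q1, hits = list(h_match)),
    list(query = q2, hits = list(h_miss))), level = "atom", scope = "all")
  expect_equal(st$overall$prop_all, 0.5)
  expect_equal(st$overall$prop_any, 0.5)
  expect_equal(st$per_query$frac_all, 0.5)
  expect_equal(st$per_kind$prop_all[st$per_kind$kind == "hbond"], 0.5)
  expect_error(shared_interaction_stats(list()), class = "mgvs_argument_error")
})

test_that("detection is invariant under rigid motion of the whole complex", {
  pc <- plant_complex(list(list(kind = "hbond", distance = 3.3, angle = 150),
                           list(kind = "pi_stack", distance = 3.8,
                                plane_angle = 10)))
  base <- detect_interactions(pc$pose, pc$receptor)
  set.seed(8)
  for (k in 1:5) {
    moved <- rigid_transform_complex(pc, runif(3, 0, 2 * pi), runif(3, -20, 20))
    got <- detect_interactions(moved$pose, moved$receptor)
    expect_identical(got[, c("kind", "prot_atoms", "residue")],
                     base[, c("kind", "prot_atoms", "residue")])
    expect_equal(got$distance, base$distance, tolerance = 1e-9)
  }
})
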
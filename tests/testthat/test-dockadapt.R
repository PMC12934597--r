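# Conformers, clustering, relaxation and the docking adapter.

test_that("conformer generation is deterministic and respects n", {
  eth <- fx_mol("CCO", "eth")
  cs1 <- generate_conformers(eth, n = 3, seed = 1)
  cs2 <- generate_conformers(eth, n = 3, seed = 1)
  expect_identical(lapply(cs1$conformers, `[[`, "atoms"),
                   lapply(cs2$conformers, `[[`, "atoms"))
  expect_gte(length(cs1$conformers), 1)

  one <- generate_conformers(fx_mol("CCCC", "but"), n = 1, seed = 2)
  expect_length(one$conformers, 1)
})

test_that("rigid aromatics collapse to near-identical conformers", {
  cs <- generate_conformers(fx_mol("c1ccccc1", "bz"), n = 5, seed = 3)
  if (length(cs$conformers) > 1) {
    for (j in 2:length(cs$conformers)) {
      expect_lt(mgvs:::pose_rmsd(cs$conformers[[1]], cs$conformers[[j]]), 0.5)
    }
  }
  cl <- cluster_conformers(cs, rmsd_cutoff = 1.0)
  expect_length(cl$conformers, 1)
})

test_that("Butina clustering follows largest-neighborhood-first on a hand matrix", {
  # 4 items: d(1,2) = 0.5, everything else >= 2; cutoff 1 -> {1,2}, {3}, {4}
  d <- matrix(2, 4, 4); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0.5
  cent <- mgvs:::butina_centroids(d, cutoff = 1)
  expect_length(cent, 3)
  expect_true(1 %in% cent || 2 %in% cent)
  expect_true(all(c(3, 4) %in% cent))

  # identical items collapse to a single centroid
  d0 <- matrix(0, 5, 5)
  expect_length(mgvs:::butina_centroids(d0, cutoff = 1), 1)

  # clustering never grows the set; singleton passes through unchanged
  cs <- generate_conformers(fx_mol("CCO", "e2"), n = 1, seed = 1)
  expect_identical(cluster_conformers(cs, 1.0), cs)
})

test_that("MMFF94 relaxation contracts a stretched bond and never raises energy", {
  cs <- generate_conformers(fx_mol("CC", "ethane"), n = 1, seed = 1)
  p <- cs$conformers[[1]]
  heavy <- which(p$atoms$element == "C")
  # stretch the C-C bond to 2.5 A by translating one methyl group
  b <- p$atoms[heavy[2], c("x", "y", "z")] - p$atoms[heavy[1], c("x", "y", "z")]
  u <- as.numeric(b) / sqrt(sum(b^2))
  half <- which(seq_len(nrow(p$atoms)) %in%
                  c(heavy[2], which(p$atoms$element == "H")[4:6]))
  shift <- (2.5 - sqrt(sum(b^2))) * u
  p$atoms[half, c("x", "y", "z")] <- sweep(p$atoms[half, c("x", "y", "z")], 2,
                                           shift, `+`)
  stretched <- cs
  stretched$conformers[[1]] <- p
  stretched$energies <- mgvs:::mmff94_energy(mgvs:::pose_to_sdf_text(p), "s")
  rel <- relax(stretched)
  q <- rel$conformers[[1]]
  cc <- sqrt(sum((q$atoms[heavy[1], c("x", "y", "z")] -
                    q$atoms[heavy[2], c("x", "y", "z")])^2))
  expect_lt(cc, 1.8)
  expect_lte(rel$energies[1], stretched$energies[1] + 1e-6)

  # already-minimized input is a fixed point up to tolerance
  rel2 <- relax(rel)
  expect_lt(abs(rel2$energies[1] - rel$energies[1]), 0.5)
})

test_that("mock engine scoring is deterministic and penalizes out-of-box poses", {
  rec <- fx_receptor()
  m <- fx_mol("CC(C)Cc1ccc(cc1)C(C)C(=O)O", "ibu")
  cs <- cluster_conformers(generate_conformers(m, n = 3, seed = 4))
  eng <- mock_engine(7)
  r1 <- score_pose(cs, rec, eng)
  r2 <- score_pose(cs, rec, eng)
  expect_identical(lapply(r1, `[[`, "vina"), lapply(r2, `[[`, "vina"))
  expect_length(r1, length(cs$conformers))
  for (r in r1) expect_identical(r$vina_eff, r$vina / n_heavy_atoms(m))

  # moving a pose far outside the 20 A box costs the +10 penalty
  far <- cs$conformers[[1]]
  far$atoms[, c("x", "y", "z")] <- far$atoms[, c("x", "y", "z")] + 100
  s_in <- mock_score(m, cs$conformers[[1]], rec, rng_seed = 7)
  s_out <- mock_score(m, far, rec, rng_seed = 7)
  expect_equal(s_out - s_in, 10)
})

test_that("best_result picks the minimum score with conformer-index ties", {
  mk <- function(v, k) structure(list(id = "x", conformer = k, pose = NULL,
                                      vina = v, vina_eff = v / 10,
                                      engine = "mock"),
                                 class = "mgvs_docking_result")
  expect_equal(best_result(list(mk(-7.1, 1), mk(-8.0, 2), mk(-6.5, 3)))$vina, -8.0)
  expect_equal(best_result(list(mk(-5, 1)))$conformer, 1)
  expect_equal(best_result(list(mk(-8, 2), mk(-8, 1)))$conformer, 1)
  expect_error(best_result(list()), class = "mgvs_argument_error")
})

test_that("score metrics are exact arithmetic", {
  expect_equal(vina_efficiency(-8.4, 28), -0.3)
  expect_equal(vina_efficiency(0, 10), 0)
  expect_equal(vina_efficiency(-9.0, 30), -0.3)
  expect_error(vina_efficiency(-8, 0), class = "mgvs_argument_error")
  expect_equal(delta_vina(-9.5, -8.0), -1.5)
  expect_equal(delta_vina(-8, -8), 0)
  expect_equal(delta_vina(-7.0, -8.0), 1.0)
})

test_that("pose SDF round-trip preserves coordinates, bonds and formal charges", {
  pc <- plant_complex(list(list(kind = "salt_bridge", distance = 3.8)))
  txt <- mgvs:::pose_to_sdf_text(pc$pose)
  back <- mgvs:::pose_from_sdf_text(txt, pc$pose$id)
  expect_equal(back$atoms$element, pc$pose$atoms$element)
  expect_equal(back$atoms$charge, pc$pose$atoms$charge) # the N+ survives
  expect_equal(back$atoms$x, pc$pose$atoms$x, tolerance = 1e-4)
  expect_equal(nrow(back$bonds), nrow(pc$pose$bonds))
  # and the charged-group interaction is still detected after the round-trip
  ints <- detect_interactions(back, pc$receptor)
  expect_equal(ints$kind, "salt_bridge")
})

test_that("the engine output parser reads both Vina grammars and rejects noise", {
  table_out <- paste(
    "mode |   affinity | dist from best mode",
    "     | (kcal/mol) | rmsd l.b.| rmsd u.b.",
    "-----+------------+----------+----------",
    "   1       -7.4        0.000      0.000",
    "   2       -7.1        1.512      2.104", sep = "\n")
  expect_equal(parse_vina_output(table_out), -7.4)
  remark <- "REMARK VINA RESULT:    -8.23      0.000      0.000"
  expect_equal(parse_vina_output(remark), -8.23)
  expect_error(parse_vina_output("garbage with no scores", "molX"),
               class = "mgvs_engine_error")
  expect_error(vina_engine("/no/such/binary"), class = "mgvs_config_error")
})
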
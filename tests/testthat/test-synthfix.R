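# Synthetic fixture generators.

test_that("toy libraries honor the edit radius as a GED bound", {
  seeds <- c(bz = "c1ccccc1", pent = "CCCCC")
  lib0 <- make_library(seeds, edit_radius = 0, n_members = 8, rng_seed = 5)
  for (i in seq_along(lib0$members)) {
    m <- lib0$members[[i]]
    s <- fx_mol(seeds[[lib0$provenance$seed_id[i]]])
    expect_equal(exact_ged(anonymize(m), anonymize(s), 2), 0)
  }
  lib1 <- make_library(c(bz = "c1ccccc1"), edit_radius = 1, n_members = 10,
                       rng_seed = 6)
  for (i in seq_along(lib1$members)) {
    d <- exact_ged(anonymize(lib1$members[[i]]),
                   anonymize(fx_mol("c1ccccc1")), 3)
    expect_lte(d, lib1$provenance$n_edits[i])
  }
})

test_that("library generation is reproducible and members are valid", {
  seeds <- c(a = "CCOc1ccccc1", b = "C1CCNCC1")
  l1 <- make_library(seeds, edit_radius = 2, n_members = 15, rng_seed = 9)
  l2 <- make_library(seeds, edit_radius = 2, n_members = 15, rng_seed = 9)
  expect_identical(vapply(l1$members, `[[`, "", "smiles"),
                   vapply(l2$members, `[[`, "", "smiles"))
  l3 <- make_library(seeds, edit_radius = 2, n_members = 15, rng_seed = 10)
  expect_false(identical(vapply(l1$members, `[[`, "", "smiles"),
                         vapply(l3$members, `[[`, "", "smiles")))
  for (m in l1$members) expect_gte(n_heavy_atoms(m), 1)
  expect_error(make_library(c(x = "C1CC"), 1, 3, 1), class = "mgvs_parse_error")
})

test_that("mock scores are pure functions of identity, receptor and seed", {
  rec <- fx_receptor()
  m1 <- parse_molecule("CCOC", "id_one")
  m2 <- parse_molecule("CCOC", "id_two") # same structure, different id
  expect_identical(mock_score(m1, NULL, rec, 3), mock_score(m1, NULL, rec, 3))
  expect_identical(mock_score(m1, NULL, rec, 3), mock_score(m2, NULL, rec, 3))
  expect_false(identical(mock_score(m1, NULL, rec, 3),
                         mock_score(m1, NULL, rec, 4)))
  # zero perturbation leaves the pure size term
  expect_equal(mock_score(fx_mol("CCCCCCCCCC", "c10"), NULL, rec,
                          rng_seed = 1, perturb = 0), -3.0)
  expect_equal(mock_score(fx_mol("CCCCCCCCCCCCCCCCCCCC", "c20"), NULL, rec,
                          rng_seed = 1, perturb = 0), -6.0)
  # perturbation is bounded by +/- perturb
  for (s in c("CCO", "c1ccccc1", "CCCCN")) {
    m <- fx_mol(s)
    dev <- mock_score(m, NULL, rec, 11) - (-0.3 * n_heavy_atoms(m))
    expect_lte(abs(dev), 1.5)
  }
  # bias table shifts exactly the designated molecule
  b <- stats::setNames(-5, m1$smiles)
  expect_equal(mock_score(m1, NULL, rec, 3, bias = b) -
                 mock_score(m1, NULL, rec, 3), -5)
})

test_that("mock scores correlate with size, making efficiency ranking meaningful", {
  rec <- fx_receptor()
  sizes <- c(5, 10, 15, 20, 25, 30)
  smis <- vapply(sizes, function(n) paste(rep("C", n), collapse = ""), "")
  vinas <- vapply(seq_along(smis), function(i)
    mock_score(fx_mol(smis[i], paste0("s", i)), NULL, rec, 2), 1.0)
  expect_lt(stats::cor(sizes, vinas), -0.9)
})

test_that("planted complexes self-check their realized geometry", {
  pc <- plant_complex(list(list(kind = "hbond", distance = 3.4, angle = 160),
                           list(kind = "pi_cation", distance = 3.9)))
  expect_true(all(abs(pc$realized$real_dist - pc$realized$target_dist) <= 0.05))
  ang <- pc$realized[!is.na(pc$realized$target_angle), ]
  expect_true(all(abs(ang$real_angle - ang$target_angle) <= 2))
  expect_error(plant_complex(list(list(kind = "wormhole", distance = 3))),
               class = "mgvs_argument_error")
  expect_error(plant_complex(list(list(kind = "hbond", distance = -1))),
               class = "mgvs_argument_error")
})

test_that("fixture emission writes regenerable plain-text files", {
  dir <- withr::local_tempdir()
  paths <- write_fixtures("full-run", seed = 3, dir = dir)
  expect_true(all(file.exists(file.path(dir, c("library.smi", "generated.smi",
                                               "receptor.pdb", "run.yaml")))))
  lib <- read_smiles_file(file.path(dir, "library.smi"))
  expect_gt(length(lib), 0)
  rec <- read_receptor(file.path(dir, "receptor.pdb"))
  expect_s3_class(rec, "mgvs_receptor")
  # regeneration from the same seed is byte-identical
  dir2 <- withr::local_tempdir()
  write_fixtures("full-run", seed = 3, dir = dir2)
  expect_identical(readLines(file.path(dir, "library.smi")),
                   readLines(file.path(dir2, "library.smi")))
})
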
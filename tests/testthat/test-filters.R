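# Compound filter rules.

test_that("cumulated double bonds are flagged, conjugation and aromatics are not", {
  expect_false(is.null(cumulated_double_bond_check(fx_mol("C=C=C", "allene"))))
  expect_false(is.null(cumulated_double_bond_check(fx_mol("CC(=C=C)C", "sub_allene"))))
  expect_null(cumulated_double_bond_check(fx_mol("C=CC=C", "butadiene")))
  expect_null(cumulated_double_bond_check(fx_mol("c1ccccc1", "bz")))
  expect_null(cumulated_double_bond_check(fx_mol("c1ccc2ccccc2c1", "naph")))
})

test_that("ring rules: sizes, fused-system count, and bridged loops", {
  expect_length(ring_system_check(fx_mol("C1CCCCC1", "chx")), 0)
  v <- ring_system_check(fx_mol("C1CCCCCC1", "chept"))
  expect_equal(vapply(v, `[[`, "", "rule"), "ring_size")
  # steroid skeleton: 4 fused rings of sizes 5/6, linear adjacency -> clean
  expect_length(ring_system_check(fx_mol("C1CC2CCC3C(CCC4CCCCC34)C2C1", "gonane")), 0)
  # adamantane: 3 smallest rings, pairwise fused -> adjacency triangle
  v2 <- ring_system_check(fx_mol("C1C2CC3CC1CC(C2)C3", "adam"))
  expect_true("ring_loop" %in% vapply(v2, `[[`, "", "rule"))
  # five linearly fused six-rings exceed the 4-ring budget
  v3 <- ring_system_check(fx_mol("c1ccc2cc3cc4cc5ccccc5cc4cc3cc2c1", "pentacene"))
  expect_true("fused_count" %in% vapply(v3, `[[`, "", "rule"))
  # configurable: allow 7-rings
  expect_length(ring_system_check(fx_mol("C1CCCCCC1", "chept"),
                                  allowed_sizes = 5:7), 0)
})

test_that("PAINS matching returns pattern names; empty catalog passes all", {
  expect_length(pains_check(fx_mol("CCO", "eth")), 0)
  hits <- pains_check(fx_mol("Oc1ccccc1O", "catechol"))
  expect_true("pains_catechol" %in% hits)
  empty <- data.frame(smarts = character(0), name = character(0))
  expect_length(pains_check(fx_mol("Oc1ccccc1O", "catechol"), empty), 0)
})

test_that("malformed PAINS catalog entries raise a configuration error", {
  f <- withr::local_tempfile(fileext = ".smarts")
  writeLines(c("[OX2H]c1ccccc1[OX2H]\tok", "no_tab_field"), f)
  expect_error(mgvs:::load_smarts_catalog(f), class = "mgvs_config_error")
  writeLines(c("[[[bad\tbroken"), f)
  expect_error(mgvs:::load_smarts_catalog(f), class = "mgvs_config_error")
})

test_that("drug-likeness ranges flag each property independently", {
  m <- fx_mol("CC(C)Cc1ccc(cc1)C(C)C(=O)O", "ibu") # mw 206
  expect_length(drug_like_check(m, list(mw = c(150, 500))), 0)
  v <- drug_like_check(m, list(mw = c(300, 500)))
  expect_equal(vapply(v, `[[`, "", "rule"), "property:mw")
  expect_length(drug_like_check(m, list(mw = c(-Inf, Inf),
                                        logp = c(-Inf, Inf))), 0)
  expect_error(drug_like_check(m, list(mw = c(500, 150))),
               class = "mgvs_config_error")
  expect_error(drug_like_check(m, list(not_a_prop = c(0, 1))),
               class = "mgvs_config_error")
})

test_that("filter stack composes rules, preserves order, and is idempotent", {
  mols <- list(fx_mol("CCCCc1ccc(CCCC)c(C2CCCCC2)c1", "clean"),
               fx_mol("C=C=C", "allene"),
               fx_mol("C1CCCCCC1", "chept"))
  cfg <- default_filter_config()
  cfg$ranges <- list(mw = c(0, 1000)) # structural rules under test
  res <- apply_filter_stack(mols, cfg)
  expect_equal(vapply(res$survivors, `[[`, "", "id"), "clean")
  expect_equal(res$reports$passed, c(TRUE, FALSE, FALSE))
  expect_match(res$reports$failures[2], "cumulated_double_bond")
  expect_match(res$reports$failures[3], "ring_size")

  # idempotence
  res2 <- apply_filter_stack(res$survivors, cfg)
  expect_equal(length(res2$survivors), length(res$survivors))

  # permutation equivariance
  perm <- c(3, 1, 2)
  resp <- apply_filter_stack(mols[perm], cfg)
  expect_equal(resp$reports$id, res$reports$id[perm])
  expect_equal(resp$reports$passed, res$reports$passed[perm])

  # all rules disabled -> everything survives
  off <- list(cumulated_double_bond = FALSE, ring_rules = FALSE,
              pains = FALSE, properties = FALSE)
  expect_length(apply_filter_stack(mols, off)$survivors, 3)
  expect_length(apply_filter_stack(list(), cfg)$survivors, 0)
})

test_that("every reported failure names a known rule", {
  mols <- list(fx_mol("C=C=C", "a"), fx_mol("C1CCCCCC1", "b"),
               fx_mol("Oc1ccccc1O", "c"), fx_mol("C1C2CC3CC1CC(C2)C3", "d"),
               fx_mol("OCC(O)C(O)C(O)C(O)CO", "e"))
  res <- apply_filter_stack(mols)
  rules <- unlist(strsplit(res$reports$failures[!res$reports$passed], ";"))
  ok <- grepl("^(cumulated_double_bond|ring_size|fused_count|ring_loop|pains|property:[a-z_]+)$",
              rules)
  expect_true(all(ok))
})
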
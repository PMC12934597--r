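# Fingerprints and Tanimoto distances.

test_that("fingerprints are deterministic with fixed width and nonzero popcount", {
  m <- fx_mol("CC(=O)Oc1ccccc1C(=O)O", "asp")
  f1 <- path_fingerprint(m)
  f2 <- path_fingerprint(m)
  expect_identical(f1, f2)
  expect_equal(length(f1$bits), 1024)
  expect_gt(sum(f1$bits), 0)

  c1 <- circular_fingerprint(m)
  expect_identical(c1, circular_fingerprint(m))
  expect_equal(length(c1$bits), 2048)
  expect_gt(sum(c1$bits), 0)

  # single heavy atom still sets at least one bit
  expect_gt(sum(circular_fingerprint(fx_mol("C", "methane"))$bits), 0)
})

test_that("related molecules overlap without being identical", {
  bz <- fx_mol("c1ccccc1", "bz")
  tol <- fx_mol("Cc1ccccc1", "tol")
  fb <- path_fingerprint(bz)
  ft <- path_fingerprint(tol)
  expect_gt(sum(fb$bits & ft$bits), 0)
  expect_false(identical(fb$bits, ft$bits))

  e1 <- circular_fingerprint(fx_mol("CCO", "ethanol"))
  e2 <- circular_fingerprint(fx_mol("CCS", "ethanethiol"))
  expect_false(identical(e1$bits, e2$bits))
})

test_that("radius-0 circular fingerprint reduces to atom typing", {
  # propane and hexane share the same atom types at radius 0
  p0 <- circular_fingerprint(fx_mol("CCC", "c3"), radius = 0)
  h0 <- circular_fingerprint(fx_mol("CCCCCC", "c6"), radius = 0)
  expect_lte(tanimoto_distance(p0, h0), 0.5)
  # but differ at radius 2
  p2 <- circular_fingerprint(fx_mol("CCC", "c3"))
  h2 <- circular_fingerprint(fx_mol("CCCCCC", "c6"))
  expect_false(identical(p2$bits, h2$bits))
})

test_that("tanimoto distance arithmetic, bounds, and errors", {
  mk <- function(kind, idx, n = 16) {
    b <- rep(FALSE, n); b[idx] <- TRUE
    mgvs:::new_fingerprint(kind, b)
  }
  expect_equal(tanimoto_distance(mk("path", 1:4), mk("path", 1:4)), 0)
  expect_equal(tanimoto_distance(mk("path", 1:2), mk("path", 3:4)), 1)
  # |and| = 2, |or| = 4
  expect_equal(tanimoto_distance(mk("path", 1:3), mk("path", 2:4)), 0.5)
  # symmetry on molecule fingerprints
  a <- path_fingerprint(fx_mol("CCO", "e"))
  b <- path_fingerprint(fx_mol("CCCO", "p"))
  expect_identical(tanimoto_distance(a, b), tanimoto_distance(b, a))
  expect_error(tanimoto_distance(mk("path", 1), mk("circular-r2", 1)),
               class = "mgvs_argument_error")
  expect_error(tanimoto_distance(mk("path", 1, 16), mk("path", 1, 32)),
               class = "mgvs_argument_error")
})

test_that("folding preserves determinism and rejects impossible widths", {
  m <- fx_mol("c1ccncc1", "pyr")
  f512 <- path_fingerprint(m, nbits = 512)
  expect_equal(length(f512$bits), 512)
  expect_identical(f512, path_fingerprint(m, nbits = 512))
  expect_error(path_fingerprint(m, nbits = 4096), class = "mgvs_argument_error")
  expect_error(path_fingerprint(m, nbits = 1000), class = "mgvs_argument_error")
})
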
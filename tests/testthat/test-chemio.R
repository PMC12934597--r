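# Molecule and receptor I/O.

test_that("SMILES parsing perceives atoms, aromaticity and charges", {
  bz <- fx_mol("c1ccccc1", "bz")
  expect_equal(n_heavy_atoms(bz), 6)
  expect_true(all(bz$atoms$aromatic))

  eth <- fx_mol("CCO", "eth")
  expect_equal(n_heavy_atoms(eth), 3)
  expect_false(any(eth$atoms$aromatic))

  asp <- fx_mol("CC(=O)Oc1ccccc1C(=O)O", "asp")
  expect_equal(n_heavy_atoms(asp), 13) # counted by hand from the SMILES

  chg <- fx_mol("[O-]C(=O)Cc1cc[n+](C)cc1", "chg")
  expect_equal(sort(chg$atoms$charge[chg$atoms$charge != 0]), c(-1L, 1L))
})

test_that("malformed and empty input raises a parse error naming the record", {
  expect_error(parse_molecule("C1CC", "badring"), "badring",
               class = "mgvs_parse_error")
  expect_error(parse_molecule("", "blank"), class = "mgvs_parse_error")
  expect_error(parse_molecule("not_a_smiles!!", "junk"),
               class = "mgvs_parse_error")
})

test_that("explicit hydrogens are folded into the heavy-atom graph", {
  m <- parse_molecule("[H]OC([H])([H])[H]", "meoh")
  expect_equal(n_heavy_atoms(m), 2)
  expect_equal(nrow(m$bonds), 1)
  expect_identical(canonical_smiles(m), canonical_smiles(fx_mol("CO", "meoh2")))
})

test_that("canonical SMILES round-trips for a diverse panel", {
  panel <- c("CCO", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O",
             "C1C2CC3CC1CC(C2)C3", "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
             "[O-]C(=O)c1ccccc1", "CC(C)Cc1ccc(cc1)C(C)C(=O)O")
  for (s in panel) {
    m1 <- parse_molecule(s, "a")
    m2 <- parse_molecule(canonical_smiles(m1), "b")
    expect_identical(canonical_smiles(m2), canonical_smiles(m1))
  }
})

test_that("property computation is deterministic and fields are in range", {
  m <- fx_mol("CC(C)Cc1ccc(cc1)C(C)C(=O)O", "ibu")
  p1 <- compute_properties(m)
  p2 <- compute_properties(m)
  expect_identical(p1, p2)
  expect_gte(p1$qed, 0); expect_lte(p1$qed, 1)
  expect_gte(p1$sa, 1); expect_lte(p1$sa, 10)
  expect_equal(p1$heavy_atoms, 15)

  pe <- compute_properties(fx_mol("CCO", "eth"))
  expect_equal(pe$hbd, 1)
  expect_equal(pe$hba, 1)
  expect_equal(compute_properties(fx_mol("c1ccccc1", "bz"))$rot_bonds, 0)
})

test_that("SMILES file reading enforces unique ids and keeps order", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO\te1", "c1ccccc1\tb1", "# comment", "CCC"), f)
  mols <- read_smiles_file(f)
  expect_named(mols, c("e1", "b1", "mol0003"))
  writeLines(c("CCO\tdup", "CCC\tdup"), f)
  expect_error(read_smiles_file(f), class = "mgvs_input_error")
})

make_pdb <- function(with_elem = TRUE, with_water = TRUE) {
  ln <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00",
    "ATOM      3  C   ALA A   1      13.142   6.229  -5.159  1.00  0.00",
    "ATOM      4  O   ALA A   1      13.712   6.746  -6.119  1.00  0.00",
    "ATOM      5  N   SER A   2      13.800   5.800  -4.080  1.00  0.00",
    "ATOM      6  CA  SER A   2      15.240   5.900  -3.980  1.00  0.00",
    "ATOM      7  OG  SER A   2      15.900   4.700  -4.300  1.00  0.00",
    "ATOM      8  N   GLY B   5      20.000   1.000   0.000  1.00  0.00",
    "ATOM      9  CA  GLY B   5      21.400   1.100   0.100  1.00  0.00")
  if (with_elem) {
    elems <- c("N", "C", "C", "O", "N", "C", "O", "N", "C")
    ln <- paste0(ln, "          ", formatC(elems, width = 2))
  }
  if (with_water) {
    ln <- c(ln, "HETATM   10  O   HOH A 101       1.000   2.000   3.000  1.00  0.00           O")
  }
  paste(c(ln, "END"), collapse = "\n")
}

test_that("receptor reading keeps protein atoms, drops waters, infers elements", {
  rec <- read_receptor(make_pdb(), box_center = c(0, 0, 0), box_edge = 20)
  expect_s3_class(rec, "mgvs_receptor")
  expect_equal(length(unique(receptor_residue_keys(rec))), 3)
  expect_false(any(rec$atoms$resid == "HOH"))
  # coordinates preserved to PDB precision
  expect_equal(rec$atoms$x[rec$atoms$elety == "OG"], 15.900)

  # blank element column: inferred from atom names, matching the
  # element-annotated parse of the same fixture
  rec2 <- read_receptor(make_pdb(with_elem = FALSE))
  ref <- read_receptor(make_pdb(with_elem = TRUE))
  heavy2 <- rec2$atoms[rec2$atoms$elesy != "H", ]
  heavyr <- ref$atoms[ref$atoms$elesy != "H", ]
  expect_identical(heavy2$elesy, heavyr$elesy)
  expect_identical(heavy2$elesy[heavy2$elety == "CA"],
                   rep("C", sum(heavy2$elety == "CA")))
})

test_that("degenerate receptor input errors cleanly", {
  expect_error(read_receptor("HEADER only\nEND", box_center = c(0, 0, 0)),
               class = "mgvs_empty_structure_error")
  water_only <- "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O\nEND"
  expect_error(read_receptor(water_only), class = "mgvs_empty_structure_error")
  expect_error(read_receptor(make_pdb(), box_edge = -1),
               class = "mgvs_argument_error")
})
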
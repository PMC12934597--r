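# Shared fixtures, built in code and memoized for the session.

.fix <- new.env(parent = emptyenv())

fx_mol <- function(smiles, id = smiles) {
  key <- paste0("mol:", smiles, ":", id)
  if (is.null(.fix[[key]])) .fix[[key]] <- parse_molecule(smiles, id)
  .fix[[key]]
}

path_graph <- function(n) {
  mgvs:::anon_graph(n, if (n > 1) cbind(seq_len(n - 1), seq(2, n)) else NULL)
}

cycle_graph <- function(n) {
  mgvs:::anon_graph(n, rbind(cbind(seq_len(n - 1), seq(2, n)), c(n, 1)))
}

# random connected molecule-like anonymous graph: random tree plus up to
# `extra` ring-closing edges
random_anon_graph <- function(n, extra = 1L) {
  e <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L))
  for (k in seq_len(sample.int(extra + 1L, 1L) - 1L)) {
    pair <- sort(sample.int(n, 2L))
    e <- rbind(e, pair)
  }
  mgvs:::anon_graph(n, e)
}

# apply a random rigid rotation + translation to pose and receptor jointly
rigid_transform_complex <- function(pc, angles, shift) {
  rot1 <- function(a, axis) {
    c1 <- cos(a); s1 <- sin(a)
    if (axis == 1) matrix(c(1, 0, 0, 0, c1, -s1, 0, s1, c1), 3, byrow = TRUE)
    else if (axis == 2) matrix(c(c1, 0, s1, 0, 1, 0, -s1, 0, c1), 3, byrow = TRUE)
    else matrix(c(c1, -s1, 0, s1, c1, 0, 0, 0, 1), 3, byrow = TRUE)
  }
  R <- rot1(angles[1], 1) %*% rot1(angles[2], 2) %*% rot1(angles[3], 3)
  tfm <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
    df[, c("x", "y", "z")] <- sweep(xyz, 2, shift, `+`)
    df
  }
  pc$pose$atoms <- tfm(pc$pose$atoms)
  pc$receptor$atoms <- tfm(pc$receptor$atoms)
  pc$receptor$box_center <- as.numeric(R %*% pc$receptor$box_center) + shift
  pc
}

# deterministic toy receptor shared by docking/pipeline tests
fx_receptor <- function() {
  if (is.null(.fix$receptor)) {
    .fix$receptor <- plant_complex(list(
      list(kind = "hbond", distance = 3.2, angle = 160)))$receptor
  }
  .fix$receptor
}

# synthetic random interaction table for match-level tests
random_interactions <- function(n) {
  kinds <- sample(c("hbond", "hydrophobic", "salt_bridge", "pi_cation",
                    "pi_stack"), n, replace = TRUE)
  res <- sample(sprintf("A:%d:RES", 1:6), n, replace = TRUE)
  atom <- paste0(res, ":", sample(c("O", "N", "OD1", "OD2", "NZ", "CB"),
                                  n, replace = TRUE))
  data.frame(kind = kinds, lig_atoms = as.character(seq_len(n)),
             prot_atoms = atom, residue = res,
             distance = stats::runif(n, 2, 4), angle = NA_real_,
             subtype = NA_character_, stringsAsFactors = FALSE)
}
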
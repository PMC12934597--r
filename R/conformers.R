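# Conformer generation, Butina clustering and MMFF94 relaxation.
#
# 3D embedding and force-field work are delegated to OpenBabel. The base
# conformer comes from the deterministic single-solution 3D builder;
# additional conformers are produced by seeded torsion driving around
# rotatable bonds followed by MMFF94 relaxation, so the whole chain is
# reproducible for a fixed seed.

new_pose <- function(id, atoms, bonds) {
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  structure(list(id = id, atoms = atoms, bonds = bonds), class = "mgvs_pose")
}

#' @export
print.mgvs_pose <- function(x, ...) {
  cat(sprintf("<pose %s: %d atoms (%d heavy)>\n", x$id, nrow(x$atoms),
              sum(x$atoms$element != "H")))
  invisible(x)
}

pose_from_sdf_text <- function(txt, id) {
  path <- tempfile(fileext = ".sdf")
  writeLines(txt, path)
  on.exit(unlink(path))
  sdfset <- ChemmineR::read.SDFset(path)
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  charges <- rep(0L, nrow(ab))
  if ("C6" %in% colnames(ab)) {
    code <- as.character(as.integer(ab[, "C6"]))
    known <- code %in% names(V2000_CHARGE_CODES)
    charges[known] <- V2000_CHARGE_CODES[code[known]]
  }
  # read M CHG from the raw input: ChemmineR's SDF container drops the
  # property block lines on round-trip
  for (ln in grep("^M  CHG", txt, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[ ]+")[[1]])
    for (k in seq_len(f[1])) charges[f[2 * k]] <- f[2 * k + 1]
  }
  nb <- if (is.null(dim(bb)) || ncol(bb) < 3L) 0L else nrow(bb)
  bonds <- if (nb > 0L) {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  } else data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  arom <- rep(FALSE, length(elements))
  ri <- tryCatch(suppressWarnings(ChemmineR::rings(sdf, type = "all", arom = TRUE)),
                 error = function(e) NULL)
  if (!is.null(ri) && length(ri$RINGS)) {
    for (k in seq_along(ri$RINGS)) {
      if (isTRUE(ri$AROMATIC[[k]])) {
        arom[match(ri$RINGS[[k]], rownames(ab))] <- TRUE
      }
    }
  }
  atoms <- data.frame(element = elements, charge = charges,
                      x = as.numeric(ab[, 1]), y = as.numeric(ab[, 2]),
                      z = as.numeric(ab[, 3]), aromatic = arom,
                      stringsAsFactors = FALSE)
  new_pose(id, atoms, bonds)
}

pose_to_sdf_text <- function(pose, tags = list()) {
  n <- nrow(pose$atoms)
  m <- nrow(pose$bonds)
  lines <- c(pose$id, "  mgvs", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              pose$atoms$x[i], pose$atoms$y[i], pose$atoms$z[i],
                              pose$atoms$element[i]))
  }
  for (i in seq_len(m)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", pose$bonds$a1[i],
                              pose$bonds$a2[i], pose$bonds$order[i]))
  }
  chg <- which(pose$atoms$charge != 0L)
  if (length(chg)) {
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste0(sprintf("%4d%4d", chg, pose$atoms$charge[chg]),
                                    collapse = "")))
  }
  lines <- c(lines, "M  END")
  for (tg in names(tags)) {
    lines <- c(lines, sprintf("> <%s>", tg), as.character(tags[[tg]]), "")
  }
  c(lines, "$$$$")
}

#' Write poses (with score tags) to an SDF file
#' @param results list of docking results (or bare `mgvs_pose` objects).
#' @param path output file.
#' @export
write_poses_sdf <- function(results, path) {
  out <- character(0)
  for (r in results) {
    if (inherits(r, "mgvs_pose")) {
      out <- c(out, pose_to_sdf_text(r))
    } else {
      out <- c(out, pose_to_sdf_text(r$pose, tags = list(
        vina = fmt_num(r$vina), vina_eff = fmt_num(r$vina_eff),
        engine = r$engine)))
    }
  }
  writeLines(out, path)
  invisible(path)
}

obabel_transform <- function(sdf_lines, args, id) {
  fin <- tempfile(fileext = ".sdf")
  fout <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(fin, fout)))
  writeLines(sdf_lines, fin)
  run_obabel(c(fin, "-osdf", args, "-O", fout))
  if (!file.exists(fout) || !length(readLines(fout, warn = FALSE))) {
    abort_mgvs(sprintf("obabel produced no output for '%s'", id),
               "mgvs_engine_error")
  }
  readLines(fout, warn = FALSE)
}

mmff94_energy <- function(sdf_lines, id) {
  fin <- tempfile(fileext = ".sdf")
  on.exit(unlink(fin))
  writeLines(sdf_lines, fin)
  exe <- Sys.which("obenergy")
  if (!nzchar(exe)) return(NA_real_)
  out <- suppressWarnings(system2(exe, c("-ff", "MMFF94", fin),
                                  stdout = TRUE, stderr = TRUE))
  ln <- grep("^TOTAL ENERGY", out, value = TRUE)
  if (!length(ln)) return(NA_real_)
  as.numeric(sub(".*=\\s*(-?[0-9.]+).*", "\\1", ln[[length(ln)]]))
}

# rotatable bonds of a pose: acyclic single bonds between heavy atoms that
# both have >= 2 heavy neighbors
pose_rotatable_bonds <- function(pose) {
  el <- pose$atoms$element
  b <- pose$bonds
  heavy <- el != "H"
  hdeg <- rep(0L, length(el))
  for (i in seq_len(nrow(b))) {
    if (heavy[b$a1[i]] && heavy[b$a2[i]]) {
      hdeg[b$a1[i]] <- hdeg[b$a1[i]] + 1L
      hdeg[b$a2[i]] <- hdeg[b$a2[i]] + 1L
    }
  }
  hv_idx <- which(heavy)
  remap <- match(seq_along(el), hv_idx)
  hb <- which(heavy[b$a1] & heavy[b$a2])
  g <- igraph::make_graph(rbind(remap[b$a1[hb]], remap[b$a2[hb]]),
                          n = length(hv_idx), directed = FALSE)
  bridge_eids <- as.integer(igraph::bridges(g))
  rot <- integer(0)
  for (k in seq_along(hb)) {
    i <- hb[k]
    if (b$order[i] != 1L) next
    if (!(k %in% bridge_eids)) next  # in a ring
    if (hdeg[b$a1[i]] < 2L || hdeg[b$a2[i]] < 2L) next
    rot <- c(rot, i)
  }
  rot
}

rotate_about_bond <- function(pose, bond_idx, angle_rad) {
  b <- pose$bonds[bond_idx, ]
  xyz <- pose_coords(pose)
  # split atoms at the bond: rotate the component containing a2
  g <- igraph::make_graph(rbind(pose$bonds$a1[-bond_idx],
                                pose$bonds$a2[-bond_idx]),
                          n = nrow(pose$atoms), directed = FALSE)
  comp <- igraph::components(g)$membership
  moving <- which(comp == comp[b$a2])
  axis_o <- xyz[b$a1, ]
  axis <- unit3(xyz[b$a2, ] - xyz[b$a1, ])
  R <- rotation_matrix(axis, angle_rad)
  xyz[moving, ] <- sweep(sweep(xyz[moving, , drop = FALSE], 2, axis_o) %*% t(R),
                         2, axis_o, `+`)
  pose$atoms$x <- xyz[, 1]; pose$atoms$y <- xyz[, 2]; pose$atoms$z <- xyz[, 3]
  pose
}

rotation_matrix <- function(axis, theta) {
  u <- unit3(axis); c1 <- cos(theta); s1 <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    c1 + ux^2 * (1 - c1), ux * uy * (1 - c1) - uz * s1, ux * uz * (1 - c1) + uy * s1,
    uy * ux * (1 - c1) + uz * s1, c1 + uy^2 * (1 - c1), uy * uz * (1 - c1) - ux * s1,
    uz * ux * (1 - c1) - uy * s1, uz * uy * (1 - c1) + ux * s1, c1 + uz^2 * (1 - c1)),
    nrow = 3, byrow = TRUE)
}

#' Generate 3D conformers for a molecule
#'
#' Embeds the molecule (hydrogens added) via a fully deterministic scheme:
#' 2D layout, seeded out-of-plane displacement to break planarity, and
#' MMFF94 relaxation. Up to `n - 1` further conformers are derived by
#' seeded torsion driving around rotatable bonds, each relaxed again.
#' Identical seeds give bit-identical coordinates. Rigid molecules yield
#' fewer distinct conformers than requested.
#'
#' @param mol a `mgvs_mol`.
#' @param n number of conformers to attempt (default 5).
#' @param seed integer seed driving the jitter and torsion sampling.
#' @return `mgvs_conformers`: list with `id`, `mol`, `conformers` (list of
#'   `mgvs_pose`), `energies` (MMFF94, kcal/mol; NA if unavailable).
#' @export
generate_conformers <- function(mol, n = 5, seed = 1L) {
  stopifnot(inherits(mol, "mgvs_mol"), n >= 1)
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(fin, fout)))
  writeLines(paste0(mol$smiles, "\t", mol$id), fin)
  run_obabel(c(fin, "-osdf", "--gen2D", "-h", "-O", fout))
  if (!file.exists(fout) || length(readLines(fout, warn = FALSE)) < 5) {
    abort_mgvs(sprintf("embedding failed for '%s'", mol$id),
               "mgvs_embed_error")
  }
  flat <- pose_from_sdf_text(readLines(fout, warn = FALSE), mol$id)
  # deterministic out-of-plane displacement so minimization can leave the
  # planar saddle (ring atoms are kept nearly in plane)
  heavy_ring <- rep(FALSE, nrow(flat$atoms))
  rb <- flat$bonds
  if (nrow(rb)) {
    g <- igraph::make_graph(rbind(rb$a1, rb$a2), n = nrow(flat$atoms),
                            directed = FALSE)
    ring_edges <- setdiff(seq_len(nrow(rb)), as.integer(igraph::bridges(g)))
    heavy_ring[unique(c(rb$a1[ring_edges], rb$a2[ring_edges]))] <- TRUE
  }
  for (i in seq_len(nrow(flat$atoms))) {
    u <- hash_unit(paste(mol$smiles, seed, "jitter", i, sep = "/"))
    amp <- if (heavy_ring[i]) 0.05 else 0.35
    flat$atoms$z[i] <- flat$atoms$z[i] + (2 * u - 1) * amp
  }
  base_lines <- minimize_lines(pose_to_sdf_text(flat), mol$id)
  base <- pose_from_sdf_text(base_lines, mol$id)
  conformers <- list(base)
  energies <- mmff94_energy(base_lines, mol$id)
  rot <- pose_rotatable_bonds(base)
  if (length(rot) && n > 1) {
    for (k in seq_len(n - 1L)) {
      cand <- base
      for (bidx in rot) {
        u <- hash_unit(paste(mol$smiles, seed, k, bidx, sep = "/"))
        ang <- (floor(u * 6) * 60 + 30) * pi / 180
        cand <- rotate_about_bond(cand, bidx, ang)
      }
      lines_k <- tryCatch(
        minimize_lines(pose_to_sdf_text(cand), mol$id),
        error = function(e) NULL)
      if (is.null(lines_k)) next
      pk <- pose_from_sdf_text(lines_k, mol$id)
      conformers[[length(conformers) + 1L]] <- pk
      energies <- c(energies, mmff94_energy(lines_k, mol$id))
    }
  }
  structure(list(id = mol$id, mol = mol, conformers = conformers,
                 energies = energies), class = "mgvs_conformers")
}

minimize_lines <- function(sdf_lines, id) {
  obabel_transform(sdf_lines, c("--minimize", "--ff", "MMFF94"), id)
}

#' @export
print.mgvs_conformers <- function(x, ...) {
  cat(sprintf("<conformers %s: %d conformer(s)>\n", x$id,
              length(x$conformers)))
  invisible(x)
}

# heavy-atom RMSD after optimal (Kabsch) superposition
pose_rmsd <- function(p1, p2) {
  h1 <- p1$atoms$element != "H"
  h2 <- p2$atoms$element != "H"
  a <- as.matrix(p1$atoms[h1, c("x", "y", "z")])
  b <- as.matrix(p2$atoms[h2, c("x", "y", "z")])
  stopifnot(nrow(a) == nrow(b))
  bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
}

#' Butina clustering of a conformer set
#'
#' Sphere-exclusion clustering on pairwise heavy-atom RMSD (after optimal
#' superposition): the conformer with the largest neighborhood within
#' `rmsd_cutoff` seeds the first cluster, its neighbors are removed, and the
#' procedure repeats. Only cluster centroids are kept.
#'
#' @param cs `mgvs_conformers`.
#' @param rmsd_cutoff neighborhood radius in Angstrom (default 1.0).
#' @return `mgvs_conformers` containing one centroid per cluster.
#' @export
cluster_conformers <- function(cs, rmsd_cutoff = 1.0) {
  stopifnot(inherits(cs, "mgvs_conformers"))
  k <- length(cs$conformers)
  if (k == 1L) return(cs)
  d <- matrix(0, k, k)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      d[i, j] <- d[j, i] <- pose_rmsd(cs$conformers[[i]], cs$conformers[[j]])
    }
  }
  keep <- butina_centroids(d, rmsd_cutoff)
  cs$conformers <- cs$conformers[keep]
  cs$energies <- cs$energies[keep]
  cs
}

# returns the indices of the cluster centroids (largest-neighborhood-first)
butina_centroids <- function(d, cutoff) {
  k <- nrow(d)
  unassigned <- rep(TRUE, k)
  centroids <- integer(0)
  repeat {
    if (!any(unassigned)) break
    sizes <- vapply(seq_len(k), function(i) {
      if (!unassigned[i]) return(-1L)
      sum(unassigned & d[i, ] <= cutoff) # includes self
    }, 1L)
    c0 <- which.max(sizes)
    centroids <- c(centroids, c0)
    unassigned[d[c0, ] <= cutoff & unassigned] <- FALSE
    unassigned[c0] <- FALSE
  }
  sort(centroids)
}

#' MMFF94 relaxation of every conformer
#'
#' Per-conformer energies are non-increasing; conformers that cannot be
#' parameterized are passed through unrelaxed with a warning.
#'
#' @param cs `mgvs_conformers`.
#' @return relaxed `mgvs_conformers`.
#' @export
relax <- function(cs) {
  stopifnot(inherits(cs, "mgvs_conformers"))
  for (i in seq_along(cs$conformers)) {
    lines_i <- pose_to_sdf_text(cs$conformers[[i]])
    out <- tryCatch(minimize_lines(lines_i, cs$id), error = function(e) NULL)
    if (is.null(out)) {
      warning(sprintf("MMFF94 parameterization failed for '%s' conformer %d; left unrelaxed",
                      cs$id, i))
      next
    }
    e_new <- mmff94_energy(out, cs$id)
    if (!is.na(e_new) && !is.na(cs$energies[i]) && e_new > cs$energies[i] + 1e-6) {
      next # keep the lower-energy original
    }
    cs$conformers[[i]] <- pose_from_sdf_text(out, cs$id)
    cs$energies[i] <- e_new
  }
  cs
}
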
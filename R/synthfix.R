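# Synthetic fixtures: toy compound libraries with known edit structure,
# planted protein-ligand complexes hitting prescribed interaction
# geometries, and a deterministic mock docking engine. Everything is
# regenerable from (specification, seed); nothing is stored as binary data.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# ---- toy libraries --------------------------------------------------------

VALENCE_CAP <- c(C = 4L, N = 3L, O = 2L, S = 2L)

mol_editor_state <- function(mol) {
  list(atoms = mol$atoms[, c("element", "charge")],
       bonds = mol$bonds[, c("a1", "a2", "order")])
}

state_free_valence <- function(st) {
  n <- nrow(st$atoms)
  used <- rep(0L, n)
  for (i in seq_len(nrow(st$bonds))) {
    used[st$bonds$a1[i]] <- used[st$bonds$a1[i]] + st$bonds$order[i]
    used[st$bonds$a2[i]] <- used[st$bonds$a2[i]] + st$bonds$order[i]
  }
  cap <- VALENCE_CAP[st$atoms$element]
  cap[is.na(cap)] <- 4L
  pmax(0L, cap - used - abs(st$atoms$charge))
}

state_degree <- function(st) {
  tabulate(c(st$bonds$a1, st$bonds$a2), nrow(st$atoms))
}

state_to_smiles <- function(st) {
  pose <- new_pose("edit", data.frame(
    element = st$atoms$element, charge = st$atoms$charge,
    x = 0, y = 0, z = 0, stringsAsFactors = FALSE), st$bonds)
  txt <- paste(pose_to_sdf_text(pose), collapse = "\n")
  can <- suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", txt))
  sub("[\t ].*$", "", sub("\n.*$", "", can))
}

# one random chemically-valid topological edit; returns NULL when the drawn
# operation is not applicable
apply_random_edit <- function(st) {
  op <- sample(c("grow", "shrink", "close", "open"), 1,
               prob = c(0.4, 0.2, 0.2, 0.2))
  fv <- state_free_valence(st)
  deg <- state_degree(st)
  n <- nrow(st$atoms)
  if (op == "grow") {
    sites <- which(fv >= 1L)
    if (!length(sites)) return(NULL)
    v <- if (length(sites) == 1L) sites else sample(sites, 1)
    st$atoms <- rbind(st$atoms, data.frame(element = "C", charge = 0L))
    st$bonds <- rbind(st$bonds, data.frame(a1 = v, a2 = n + 1L, order = 1L))
    attr(st, "edit") <- sprintf("grow@%d", v)
    return(st)
  }
  if (op == "shrink") {
    if (n <= 2L) return(NULL)
    term <- which(deg == 1L)
    if (!length(term)) return(NULL)
    v <- if (length(term) == 1L) term else sample(term, 1)
    keep <- !(st$bonds$a1 == v | st$bonds$a2 == v)
    st$bonds <- st$bonds[keep, , drop = FALSE]
    st$bonds$a1 <- st$bonds$a1 - (st$bonds$a1 > v)
    st$bonds$a2 <- st$bonds$a2 - (st$bonds$a2 > v)
    st$atoms <- st$atoms[-v, , drop = FALSE]
    attr(st, "edit") <- sprintf("shrink@%d", v)
    return(st)
  }
  if (op == "close") {
    g <- igraph::make_graph(rbind(st$bonds$a1, st$bonds$a2), n = n,
                            directed = FALSE)
    dmat <- igraph::distances(g)
    cand <- which(dmat >= 4 & dmat <= 5 & upper.tri(dmat), arr.ind = TRUE)
    if (nrow(cand)) {
      ok <- fv[cand[, 1]] >= 1L & fv[cand[, 2]] >= 1L
      cand <- cand[ok, , drop = FALSE]
    }
    if (!nrow(cand)) return(NULL)
    pick <- cand[sample(nrow(cand), 1), ]
    st$bonds <- rbind(st$bonds, data.frame(a1 = pick[1], a2 = pick[2],
                                           order = 1L))
    attr(st, "edit") <- sprintf("close@%d-%d", pick[1], pick[2])
    return(st)
  }
  # open: delete a ring (non-bridge) bond
  g <- igraph::make_graph(rbind(st$bonds$a1, st$bonds$a2), n = n,
                          directed = FALSE)
  ringb <- setdiff(seq_len(nrow(st$bonds)), as.integer(igraph::bridges(g)))
  if (!length(ringb)) return(NULL)
  i <- if (length(ringb) == 1L) ringb else sample(ringb, 1)
  attr(st, "edit") <- sprintf("open@%d-%d", st$bonds$a1[i], st$bonds$a2[i])
  st$bonds <- st$bonds[-i, , drop = FALSE]
  st
}

# free (GED-0) element relabel: C <-> N where valence allows
apply_random_relabel <- function(st) {
  fv <- state_free_valence(st)
  cN <- which(st$atoms$element == "C" & fv >= 1L & st$atoms$charge == 0L)
  nC <- which(st$atoms$element == "N" & st$atoms$charge == 0L)
  cand <- c(cN, nC)
  if (!length(cand)) return(st)
  v <- if (length(cand) == 1L) cand else sample(cand, 1)
  st$atoms$element[v] <- if (st$atoms$element[v] == "C") "N" else "C"
  st
}

#' Generate a toy compound library with known edit structure
#'
#' Members are produced from seed SMILES by random chemically valid
#' topological edits (append/remove a terminal atom, open/close a 5- or
#' 6-ring), at most `edit_radius` per member, optionally followed by
#' topology-preserving element relabels. The anonymous-graph edit distance
#' of each member to its seed is therefore bounded by the recorded edit
#' count. Fully deterministic per `rng_seed`.
#'
#' @param seeds character vector of seed SMILES (optionally named by id).
#' @param edit_radius maximum topological edits per member.
#' @param n_members library size.
#' @param rng_seed integer seed.
#' @return `mgvs_toylib`: list with `members` (list of `mgvs_mol`),
#'   `provenance` (data.frame: `id`, `seed_id`, `n_edits`, `edits`), `seeds`.
#' @export
make_library <- function(seeds, edit_radius = 2L, n_members = 50L,
                         rng_seed = 1L) {
  if (is.null(names(seeds))) {
    names(seeds) <- sprintf("seed%02d", seq_along(seeds))
  }
  seed_mols <- Map(function(s, id) parse_molecule(s, id, source = "seed"),
                   seeds, names(seeds))
  members <- vector("list", n_members)
  prov <- vector("list", n_members)
  with_seed(derive_seed(rng_seed, "toylib"), {
    for (k in seq_len(n_members)) {
      si <- ((k - 1L) %% length(seeds)) + 1L
      base <- seed_mols[[si]]
      id <- sprintf("lib%04d", k)
      for (attempt in 1:25) {
        st <- mol_editor_state(base)
        n_edits <- if (edit_radius > 0) sample(0:edit_radius, 1) else 0L
        edits <- character(0)
        ok <- TRUE
        for (e in seq_len(n_edits)) {
          st2 <- NULL
          for (tries in 1:10) {
            st2 <- apply_random_edit(st)
            if (!is.null(st2)) break
          }
          if (is.null(st2)) { ok <- FALSE; break }
          edits <- c(edits, attr(st2, "edit"))
          st <- st2
        }
        if (!ok) next
        if (stats::runif(1) < 0.5) st <- apply_random_relabel(st)
        smi <- state_to_smiles(st)
        if (!nzchar(smi) || grepl(".", smi, fixed = TRUE)) next
        m <- tryCatch(parse_molecule(smi, id, source = "library:toy"),
                      error = function(e) NULL)
        if (is.null(m)) next
        members[[k]] <- m
        prov[[k]] <- data.frame(id = id, seed_id = names(seeds)[si],
                                n_edits = length(edits),
                                edits = paste(edits, collapse = ";"),
                                stringsAsFactors = FALSE)
        break
      }
      if (is.null(members[[k]])) {
        # fall back to an unedited copy of the seed
        members[[k]] <- parse_molecule(seeds[[si]], id, source = "library:toy")
        prov[[k]] <- data.frame(id = id, seed_id = names(seeds)[si],
                                n_edits = 0L, edits = "",
                                stringsAsFactors = FALSE)
      }
    }
  })
  structure(list(members = members, provenance = do.call(rbind, prov),
                 seeds = seeds, rng_seed = rng_seed),
            class = "mgvs_toylib")
}

#' @export
print.mgvs_toylib <- function(x, ...) {
  cat(sprintf("<toy library: %d members from %d seeds (seed=%d)>\n",
              length(x$members), length(x$seeds), x$rng_seed))
  invisible(x)
}

# ---- mock docking engine --------------------------------------------------

#' Deterministic mock docking score
#'
#' Score = `-0.3 * heavy_atoms` plus a bounded pseudo-random perturbation in
#' `[-perturb, +perturb]` keyed by (canonical SMILES, receptor id, seed), so
#' identical inputs always give identical scores and records differing only
#' in id score identically. A pose whose centroid falls outside the
#' receptor's docking box is penalized by +10. The size term deliberately
#' mirrors the size bias of physical docking scores, so ranking by raw score
#' and by Vina efficiency disagree in a realistic way.
#'
#' @param mol `mgvs_mol`.
#' @param pose optional `mgvs_pose` (out-of-box check skipped when NULL).
#' @param rec `mgvs_receptor`.
#' @param rng_seed integer seed.
#' @param perturb perturbation half-width (kcal/mol); 0 disables it.
#' @param bias optional named numeric: canonical SMILES -> additive offset
#'   (fixture machinery for planting designated winners).
#' @return numeric score, kcal/mol.
#' @export
mock_score <- function(mol, pose = NULL, rec, rng_seed = 1L, perturb = 1.5,
                       bias = NULL) {
  stopifnot(inherits(mol, "mgvs_mol"))
  s <- -0.3 * n_heavy_atoms(mol)
  if (perturb > 0) {
    u <- hash_unit(paste(mol$smiles, rec$id, rng_seed, sep = "|"))
    s <- s + (2 * u - 1) * perturb
  }
  if (!is.null(pose)) {
    ctr <- colMeans(pose_coords(pose))
    if (!in_box(rec, ctr)) s <- s + 10
  }
  if (!is.null(bias) && mol$smiles %in% names(bias)) {
    s <- s + bias[[mol$smiles]]
  }
  s
}

#' Mock docking engine adapter
#'
#' Wraps [mock_score()] in the engine contract used by [score_pose()] and
#' the pipeline.
#'
#' @inheritParams mock_score
#' @return engine adapter.
#' @export
mock_engine <- function(rng_seed = 1L, perturb = 1.5, bias = NULL) {
  structure(list(
    tag = "mock",
    seed = rng_seed,
    score = function(mol, pose, rec) {
      mock_score(mol, pose, rec, rng_seed = rng_seed, perturb = perturb,
                 bias = bias)
    }), class = "mgvs_engine")
}

# ---- planted-recovery screening fixture -----------------------------------

#' Build a screening fixture with one designated best analog per query
#'
#' Constructs a generated set and a compound library such that, under the
#' mock engine with the returned bias table, the pipeline must select a
#' known query set and recover a designated analog as the best docked hit
#' of every query. The construction guarantees non-overlapping search
#' shells: query skeletons differ pairwise by more than `max_ged + 1` node
#' edits (enforced through size separation), so a designated analog (one
#' edit from its query) can never appear in another query's hit pool.
#'
#' Layout: `n_queries` size-separated scaffolds are the intended queries;
#' large decoy molecules complete the generated set (their mock Vina
#' efficiency can never beat a biased query); the library holds each
#' query's designated analog (one terminal-atom growth, biased to dominate
#' its pool), unbiased competitor variants within two edits of each query,
#' and large decoy compounds.
#'
#' @param n_queries number of designated queries (default 10).
#' @param n_generated generated-set size (default 20).
#' @param library_size library size (default 200).
#' @param max_ged search radius the fixture is built for (default 2).
#' @param rng_seed integer seed.
#' @return list: `generated`, `library` (lists of `mgvs_mol`), `bias`
#'   (named numeric for [mock_engine()]), `query_ids`, `analog_of` (named
#'   character: query id -> designated analog id), `config_hints`.
#' @export
plant_recovery_fixture <- function(n_queries = 10L, n_generated = 20L,
                                   library_size = 200L, max_ged = 2L,
                                   rng_seed = 1L) {
  stopifnot(n_generated >= n_queries, library_size >= 2L * n_queries)
  sizes <- seq(4L, by = max_ged + 2L, length.out = n_queries)
  chain <- function(n) paste(rep("C", n), collapse = "")
  queries <- Map(function(n, i) parse_molecule(chain(n), sprintf("q%02d", i),
                                               source = "generated"),
                 sizes, seq_len(n_queries))
  # decoy sizes are odd while query sizes are even multiples, so no decoy
  # can collide with a biased query structure
  decoy_gen <- lapply(seq_len(n_generated - n_queries), function(i)
    parse_molecule(chain(23L + 2L * i), sprintf("gdec%02d", i),
                   source = "generated"))
  generated <- c(queries, decoy_gen)

  taken <- vapply(generated, `[[`, "", "smiles")
  # designated analogs first: small queries admit only a couple of distinct
  # single-growth products, so analogs claim their structures before any
  # competitor variant can occupy them
  analogs <- list()
  analog_of <- character(0)
  for (i in seq_len(n_queries)) {
    q <- queries[[i]]
    placed <- FALSE
    for (site in seq_len(n_heavy_atoms(q))) {
      st <- mol_editor_state(q)
      if (state_free_valence(st)[site] < 1L) next
      st$atoms <- rbind(st$atoms, data.frame(element = "C", charge = 0L))
      st$bonds <- rbind(st$bonds, data.frame(a1 = site, a2 = nrow(st$atoms),
                                             order = 1L))
      smi <- state_to_smiles(st)
      if (!nzchar(smi) || smi %in% taken) next
      analogs[[i]] <- parse_molecule(smi, sprintf("ana%02d", i),
                                     source = "library:planted")
      analog_of[q$id] <- sprintf("ana%02d", i)
      taken <- c(taken, smi)
      placed <- TRUE
      break
    }
    if (!placed) {
      abort_mgvs(sprintf("could not place a collision-free analog for %s",
                         q$id), "mgvs_internal_error")
    }
  }
  # competitor variants: unbiased library members within max_ged of a query
  variants <- list()
  per_query_var <- max(1L, (library_size - 2L * n_queries) %/%
                         (2L * n_queries))
  for (i in seq_len(n_queries)) {
    vl <- make_library(stats::setNames(queries[[i]]$smiles,
                                       sprintf("s%02d", i)),
                       edit_radius = max_ged, n_members = per_query_var,
                       rng_seed = derive_seed(rng_seed, paste0("var", i)))
    for (k in seq_along(vl$members)) {
      m <- vl$members[[k]]
      if (m$smiles %in% taken) next
      m$id <- sprintf("var%02d_%02d", i, k)
      variants[[length(variants) + 1L]] <- m
      taken <- c(taken, m$smiles)
    }
  }
  n_fill <- library_size - length(analogs) - length(variants)
  fill <- list()
  if (n_fill > 0L) {
    fl <- make_library(c(big = chain(30L)), edit_radius = 2L,
                       n_members = n_fill,
                       rng_seed = derive_seed(rng_seed, "bigfill"))
    for (k in seq_along(fl$members)) {
      m <- fl$members[[k]]
      if (m$smiles %in% taken) next # never duplicate a biased structure
      m$id <- sprintf("dec%03d", k)
      fill[[length(fill) + 1L]] <- m
    }
  }
  library_mols <- c(analogs, variants, fill)
  bias <- c(stats::setNames(rep(-5, n_queries),
                            vapply(queries, `[[`, "", "smiles")),
            stats::setNames(rep(-8, length(analogs)),
                            vapply(analogs, `[[`, "", "smiles")))
  list(generated = generated, library = library_mols, bias = bias,
       query_ids = vapply(queries, `[[`, "", "id"), analog_of = analog_of,
       config_hints = list(max_ged = max_ged,
                           top_queries = n_queries,
                           ranges = list(mw = c(0, 1000))))
}

# ---- planted complexes ----------------------------------------------------

#' Build a protein-ligand complex realizing prescribed interactions
#'
#' Constructs a minimal receptor (isolated idealized residues) and a
#' multi-fragment ligand pose so that each requested interaction hits its
#' target distance (and angle) to within 0.05 Angstrom / 2 degrees, while
#' fragments are spaced far enough apart that no unintended contact comes
#' within 1.2x of any cutoff. The receptor is produced as PDB text and
#' parsed through [read_receptor()], so the standard reader path is
#' exercised.
#'
#' Supported entries: `list(kind = "hbond", distance =, angle =)` (ligand
#' hydroxyl donor vs serine O-gamma acceptor), `list(kind = "hydrophobic",
#' distance =)` (methane carbon vs alanine C-beta), `list(kind =
#' "salt_bridge", distance =)` (ammonium vs aspartate carboxylate
#' centroid), `list(kind = "pi_stack", distance =, plane_angle =, offset =)`
#' (benzene vs phenylalanine ring), `list(kind = "pi_cation", distance =)`
#' (benzene ring center vs lysine ammonium nitrogen).
#'
#' @param spec list of intended-interaction entries.
#' @param id complex identifier.
#' @return `mgvs_planted`: list with `receptor` (`mgvs_receptor`), `pose`
#'   (`mgvs_pose`), `intended` (the spec), `realized` (data.frame of
#'   realized geometry).
#' @export
plant_complex <- function(spec, id = "planted") {
  lig_atoms <- list(); lig_bonds <- list(); lig_arom <- c()
  prot <- list()
  realized <- list()
  resno <- 0L
  offset_y <- 0
  add_lig <- function(el, xyz, charge = 0L, aromatic = FALSE) {
    lig_atoms[[length(lig_atoms) + 1L]] <<- data.frame(
      element = el, charge = charge, x = xyz[1], y = xyz[2], z = xyz[3],
      aromatic = aromatic, stringsAsFactors = FALSE)
    length(lig_atoms)
  }
  add_bond <- function(a, b, order = 1L) {
    lig_bonds[[length(lig_bonds) + 1L]] <<- data.frame(a1 = a, a2 = b,
                                                       order = order)
  }
  add_res <- function(resid, names, coords, elements = NULL) {
    resno <<- resno + 1L
    if (is.null(elements)) elements <- infer_element(names)
    prot[[length(prot) + 1L]] <<- data.frame(
      chain = "A", resno = resno, insert = "", resid = resid,
      elety = names, elesy = elements, x = coords[, 1], y = coords[, 2],
      z = coords[, 3], stringsAsFactors = FALSE)
  }
  tetra_h <- function(center, towards, dist = 1.09) {
    # three H around `center`, tetrahedral to the bond pointing `towards`
    u <- unit3(towards)
    w1 <- unit3(pick_perp(u))
    w2 <- unit3(pracma_cross(u, w1))
    ang <- 109.5 * pi / 180
    vapply(0:2, function(k) {
      phi <- 2 * pi * k / 3
      center + dist * (cos(ang) * u + sin(ang) * (cos(phi) * w1 + sin(phi) * w2))
    }, numeric(3))
  }
  hexagon <- function(center, e1, e2, r = 1.39) {
    t(vapply(0:5, function(k) {
      center + r * (cos(pi * k / 3) * e1 + sin(pi * k / 3) * e2)
    }, numeric(3)))
  }

  for (entry in spec) {
    o <- c(0, offset_y, 0)
    kind <- entry$kind
    d <- entry$distance
    if (is.null(kind) || is.null(d) || d <= 0) {
      abort_mgvs("each planted entry needs a kind and a positive distance",
                 "mgvs_argument_error")
    }
    if (kind == "hbond") {
      theta <- (entry$angle %||% 160) * pi / 180
      C <- add_lig("C", o + c(0, 0, -1.4))
      O <- add_lig("O", o + c(0, 0, 0))
      H <- add_lig("H", o + c(0, 0, 0.97))
      add_bond(C, O); add_bond(O, H)
      for (hc in seq_len(3)) {
        hxyz <- tetra_h(o + c(0, 0, -1.4), c(0, 0, 1))[, hc]
        add_bond(add_lig("H", hxyz), C)
      }
      r <- 0.97 * cos(theta) + sqrt(max(0, 0.97^2 * cos(theta)^2 + d^2 - 0.97^2))
      A <- o + c(0, 0, 0.97) + r * c(sin(theta), 0, -cos(theta))
      u <- unit3(A - (o + c(0, 0, 0)))
      w <- unit3(pick_perp(u))
      nm <- c("OG", "HG", "CB", "CA", "N", "C", "O")
      co <- rbind(A, A + 0.97 * w, A + 1.43 * u, A + 2.95 * u,
                  A + 2.95 * u + 1.47 * w, A + 4.47 * u,
                  A + 4.47 * u + 1.23 * w)
      add_res("SER", nm, co)
      realized[[length(realized) + 1L]] <- data.frame(
        kind = kind, target_dist = d, real_dist = vdist(A, o),
        target_angle = entry$angle %||% 160,
        real_angle = dha_angle(o + c(0, 0, 0), o + c(0, 0, 0.97), A))
    } else if (kind == "hydrophobic") {
      C <- add_lig("C", o)
      hs <- tetra_h(o, c(0, 0, -1))
      for (hc in seq_len(3)) add_bond(add_lig("H", hs[, hc]), C)
      add_bond(add_lig("H", o + c(0, 0, -1.09)), C)
      B <- o + c(0, 0, d)
      u <- c(0, 0, 1)
      nm <- c("CB", "CA", "N", "C", "O")
      co <- rbind(B, B + 1.52 * u, B + 1.52 * u + c(1.47, 0, 0),
                  B + 1.52 * u + c(-1.52, 0, 0),
                  B + 1.52 * u + c(-1.52, 1.23, 0))
      add_res("ALA", nm, co)
      realized[[length(realized) + 1L]] <- data.frame(
        kind = kind, target_dist = d, real_dist = vdist(B, o),
        target_angle = NA_real_, real_angle = NA_real_)
    } else if (kind == "salt_bridge") {
      N <- add_lig("N", o, charge = 1L)
      C <- add_lig("C", o + c(0, 0, -1.49))
      add_bond(N, C)
      hs <- tetra_h(o, c(0, 0, -1), dist = 1.01)
      for (hc in seq_len(3)) add_bond(add_lig("H", hs[, hc]), N)
      for (hc in seq_len(3)) {
        hxyz <- tetra_h(o + c(0, 0, -1.49), c(0, 0, 1))[, hc]
        add_bond(add_lig("H", hxyz), C)
      }
      G <- o + c(0, 0, d) # carboxylate centroid
      nm <- c("OD1", "OD2", "CG", "CB", "CA", "N", "C", "O")
      co <- rbind(G + c(1.1, 0, 0), G + c(-1.1, 0, 0), G + c(0, 0, 0.65),
                  G + c(0, 0, 2.17), G + c(0, 0, 3.69),
                  G + c(1.47, 0, 3.69), G + c(-1.52, 0, 3.69),
                  G + c(-1.52, 1.23, 3.69))
      add_res("ASP", nm, co)
      realized[[length(realized) + 1L]] <- data.frame(
        kind = kind, target_dist = d, real_dist = vdist(G, o),
        target_angle = NA_real_, real_angle = NA_real_)
    } else if (kind == "pi_stack") {
      alpha <- (entry$plane_angle %||% 0) * pi / 180
      off <- entry$offset %||% 0
      ring <- hexagon(o, c(1, 0, 0), c(0, 1, 0))
      idx <- integer(6)
      for (k in 1:6) idx[k] <- add_lig("C", ring[k, ], aromatic = TRUE)
      for (k in 1:6) {
        add_bond(idx[k], idx[(k %% 6) + 1], order = ifelse(k %% 2 == 1, 2L, 1L))
        hpos <- o + 2.47 * unit3(ring[k, ] - o)
        add_bond(add_lig("H", hpos), idx[k])
      }
      zc <- sqrt(max(0, d^2 - off^2))
      ctr <- o + c(off, 0, zc)
      e1 <- c(1, 0, 0)
      e2 <- c(0, cos(alpha), -sin(alpha))
      pring <- hexagon(ctr, e1, e2)
      radial <- unit3(pring[1, ] - ctr)
      nm <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2", "CB", "CA", "N", "C", "O")
      co <- rbind(pring[1, ], pring[2, ], pring[3, ], pring[4, ],
                  pring[5, ], pring[6, ],
                  ctr + 2.89 * radial, ctr + 4.41 * radial,
                  ctr + 4.41 * radial + 1.47 * c(0, 0, 1),
                  ctr + 5.93 * radial,
                  ctr + 5.93 * radial + 1.23 * c(0, 0, 1))
      add_res("PHE", nm, co)
      realized[[length(realized) + 1L]] <- data.frame(
        kind = kind, target_dist = d, real_dist = vdist(ctr, o),
        target_angle = entry$plane_angle %||% 0,
        real_angle = plane_angle(c(0, 0, 1), unit3(pracma_cross(e1, e2))))
    } else if (kind == "pi_cation") {
      ring <- hexagon(o, c(1, 0, 0), c(0, 1, 0))
      idx <- integer(6)
      for (k in 1:6) idx[k] <- add_lig("C", ring[k, ], aromatic = TRUE)
      for (k in 1:6) {
        add_bond(idx[k], idx[(k %% 6) + 1], order = ifelse(k %% 2 == 1, 2L, 1L))
        add_bond(add_lig("H", o + 2.47 * unit3(ring[k, ] - o)), idx[k])
      }
      NZ <- o + c(0, 0, d)
      u <- c(0, 0, 1)
      hz <- tetra_h(NZ, -u, dist = 1.01) # H point away from the ring
      nm <- c("NZ", "HZ1", "HZ2", "HZ3", "CE", "CD", "CG", "CB", "CA",
              "N", "C", "O")
      co <- rbind(NZ, t(hz), NZ + 1.49 * u, NZ + 3.01 * u, NZ + 4.53 * u,
                  NZ + 6.05 * u, NZ + 7.57 * u, NZ + 7.57 * u + c(1.47, 0, 0),
                  NZ + 9.09 * u, NZ + 9.09 * u + c(1.23, 0, 0))
      add_res("LYS", nm, co)
      realized[[length(realized) + 1L]] <- data.frame(
        kind = kind, target_dist = d, real_dist = vdist(NZ, o),
        target_angle = NA_real_, real_angle = NA_real_)
    } else {
      abort_mgvs(sprintf("unsupported planted interaction kind '%s'", kind),
                 "mgvs_argument_error")
    }
    offset_y <- offset_y + 25
  }
  atoms <- do.call(rbind, lig_atoms)
  bonds <- do.call(rbind, lig_bonds)
  pose <- new_pose(paste0(id, "_ligand"), atoms, bonds)
  prot_df <- do.call(rbind, prot)
  # realizability: no receptor atom may collide with a ligand atom
  lxyz <- as.matrix(atoms[, c("x", "y", "z")])
  pxyz <- as.matrix(prot_df[, c("x", "y", "z")])
  for (i in seq_len(nrow(pxyz))) {
    dmin <- min(sqrt(colSums((t(lxyz) - pxyz[i, ])^2)))
    if (dmin < 1.5) {
      abort_mgvs(sprintf("unrealizable spec: receptor atom %s:%s clashes with the ligand (%.2f A)",
                         prot_df$resid[i], prot_df$elety[i], dmin),
                 "mgvs_argument_error")
    }
  }
  rec <- read_receptor(planted_pdb_text(prot_df),
                       box_center = colMeans(lxyz), box_edge = 20,
                       id = id)
  real_df <- do.call(rbind, realized)
  bad <- abs(real_df$real_dist - real_df$target_dist) > 0.05 |
    (!is.na(real_df$target_angle) &
       abs(real_df$real_angle - real_df$target_angle) > 2)
  if (any(bad)) {
    abort_mgvs(sprintf("planted geometry failed self-check for kind(s): %s",
                       paste(real_df$kind[bad], collapse = ", ")),
               "mgvs_internal_error")
  }
  structure(list(receptor = rec, pose = pose, intended = spec,
                 realized = real_df), class = "mgvs_planted")
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

planted_pdb_text <- function(df) {
  nm4 <- ifelse(nchar(df$elety) < 4, sprintf(" %-3s", df$elety), df$elety)
  paste(c(vapply(seq_len(nrow(df)), function(i) {
    sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, nm4[i], df$resid[i], df$chain[i], df$resno[i],
            df$x[i], df$y[i], df$z[i], df$elesy[i])
  }, ""), "END"), collapse = "\n")
}

#' @export
print.mgvs_planted <- function(x, ...) {
  cat(sprintf("<planted complex: %d intended interaction(s), %d receptor atoms>\n",
              length(x$intended), nrow(x$receptor$atoms)))
  invisible(x)
}

# ---- fixture emission (CLI support) ---------------------------------------

#' Write a synthetic fixture set to a directory
#'
#' Presets: `"library"` (toy library + query SMILES), `"complex"` (planted
#' receptor PDB + ligand SDF), `"full-run"` (library, generated set,
#' receptor and a run config) — all plain text, regenerable from the seed.
#'
#' @param preset one of `"library"`, `"complex"`, `"full-run"`.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_fixtures <- function(preset = c("library", "complex", "full-run"),
                           seed = 1L, dir = ".") {
  preset <- match.arg(preset)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  seeds <- c(benzofuranone = "O=C1OCc2ccccc12",
             phenylpiperidine = "C1CCN(CC1)c1ccccc1",
             toluate = "Cc1ccccc1C(=O)OC")
  if (preset %in% c("library", "full-run")) {
    lib <- make_library(seeds, edit_radius = 2L, n_members = 60L,
                        rng_seed = seed)
    p <- file.path(dir, "library.smi")
    write_smiles_file(lib$members, p)
    paths <- c(paths, p)
    gen <- make_library(seeds, edit_radius = 3L, n_members = 20L,
                        rng_seed = derive_seed(seed, "generated"))
    p2 <- file.path(dir, "generated.smi")
    write_smiles_file(gen$members, p2)
    paths <- c(paths, p2)
  }
  if (preset %in% c("complex", "full-run")) {
    pc <- plant_complex(list(
      list(kind = "hbond", distance = 3.2, angle = 160),
      list(kind = "salt_bridge", distance = 3.8),
      list(kind = "pi_stack", distance = 3.6, plane_angle = 0)))
    p3 <- file.path(dir, "receptor.pdb")
    writeLines(planted_pdb_text(pc$receptor$atoms), p3)
    p4 <- file.path(dir, "ligand.sdf")
    writeLines(pose_to_sdf_text(pc$pose), p4)
    paths <- c(paths, p3, p4)
  }
  if (preset == "full-run") {
    cfg <- list(generated = "generated.smi", library = "library.smi",
                receptor = "receptor.pdb", engine = "mock", seed = seed,
                top_queries = 5, max_ged = 4, max_raw_hits = 100,
                top_hits_per_query = 10)
    p5 <- file.path(dir, "run.yaml")
    yaml::write_yaml(cfg, p5)
    paths <- c(paths, p5)
  }
  invisible(paths)
}
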
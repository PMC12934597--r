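# Geometric protein-ligand interaction detection and query/hit interaction
# matching.
#
# Five interaction types are detected from explicit geometry: hydrogen bonds
# (donor-acceptor heavy-atom distance AND donor-H-acceptor angle),
# hydrophobic contacts (apolar carbon pairs), salt bridges (charged-group
# centroids), pi-stacking (ring centers, plane angles, lateral offset), and
# pi-cation (ring center to cation). All cutoff comparisons are inclusive
# (<= for distances, >= for angles), so a contact planted exactly at a
# cutoff is detected.

#' Interaction geometry cutoffs
#'
#' Distance cutoffs in Angstrom, angles in degrees. Defaults: hydrogen bond
#' 3.5 A with a minimum 120 degree D-H-A angle; hydrophobic carbon contact
#' 3.8 A; salt bridge 4.0 A between group centroids; pi-stacking 4.0 A
#' center-center (parallel, plane angle <= 30) or 5.5 A (perpendicular,
#' plane angle 50-90) with lateral ring offset <= 2.0 A; pi-cation 4.0 A
#' center-cation.
#'
#' @param ... overrides of the named defaults.
#' @return list of cutoffs.
#' @export
default_cutoffs <- function(...) {
  cut <- list(hbond_dist = 3.5, hbond_angle = 120,
              hydrophobic_dist = 3.8, salt_dist = 4.0,
              pistack_parallel_dist = 4.0, pistack_perp_dist = 5.5,
              pication_dist = 4.0,
              pistack_parallel_angle = 30, pistack_perp_angle = c(50, 90),
              pistack_offset = 2.0,
              merge_pistack_geometries = TRUE)
  over <- list(...)
  for (k in names(over)) cut[[k]] <- over[[k]]
  stopifnot(all(unlist(cut[grepl("dist|offset", names(cut))]) > 0))
  cut
}

#' Read interaction cutoffs from YAML
#' @param path YAML file; missing fields take defaults.
#' @return cutoff list.
#' @export
read_cutoffs <- function(path) {
  user <- yaml::read_yaml(path)
  do.call(default_cutoffs, user)
}

SPECIFIC_KINDS <- c("hbond", "salt_bridge", "pi_cation", "pi_stack")

vdist <- function(a, b) sqrt(sum((a - b)^2))

angle_deg <- function(v1, v2) {
  c1 <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(min(1, max(-1, c1))) * 180 / pi
}

# angle at H between donor and acceptor
dha_angle <- function(D, H, A) angle_deg(D - H, A - H)

# Best achievable D-H-A angle for a rotatable donor: H lies on the cone
# around the antecedent->donor axis at the tetrahedral angle; the in-plane
# position closest to the acceptor is optimal and computed analytically.
rotatable_dha <- function(D, Ante, Acc, dh = 0.97, theta_deg = 109.5) {
  u <- unit3(D - Ante)               # axis away from the antecedent
  v <- Acc - D
  vpar <- sum(v * u) * u
  vperp <- v - vpar
  cone <- (180 - theta_deg) * pi / 180  # H direction vs axis
  if (sqrt(sum(vperp^2)) < 1e-9) {
    w <- unit3(pick_perp(u))
  } else {
    w <- unit3(vperp)
  }
  h <- cos(cone) * u + sin(cone) * w
  H <- D + dh * h
  dha_angle(D, H, A = Acc)
}

pick_perp <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  ref - sum(ref * u) * u
}

# least-squares ring plane: centroid + unit normal
ring_plane <- function(coords) {
  ctr <- colMeans(coords)
  sv <- svd(sweep(coords, 2, ctr))
  list(center = ctr, normal = sv$v[, 3])
}

plane_angle <- function(n1, n2) {
  a <- angle_deg(n1, n2)
  min(a, 180 - a)
}

ring_offset <- function(p1, p2) {
  # lateral displacement: projection of the center-center vector onto each
  # ring plane; the smaller of the two is used
  d <- p2$center - p1$center
  off1 <- sqrt(max(0, sum(d^2) - sum(d * p1$normal)^2))
  off2 <- sqrt(max(0, sum(d^2) - sum(d * p2$normal)^2))
  min(off1, off2)
}

# ---- ligand typing --------------------------------------------------------

pose_coords <- function(pose) as.matrix(pose$atoms[, c("x", "y", "z")])

lig_neighbors <- function(pose) {
  n <- nrow(pose$atoms)
  nb <- vector("list", n)
  for (i in seq_len(nrow(pose$bonds))) {
    a <- pose$bonds$a1[i]; b <- pose$bonds$a2[i]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  nb
}

ligand_typing <- function(pose) {
  el <- pose$atoms$element
  chg <- pose$atoms$charge %||% rep(0L, length(el))
  if (!any(el == "H")) {
    abort_mgvs("ligand pose lacks explicit hydrogens (required for H-bond angles)",
               "mgvs_precondition_error")
  }
  nb <- lig_neighbors(pose)
  has_h <- vapply(seq_along(el), function(i) any(el[nb[[i]]] == "H"), TRUE)
  heavy_nb <- lapply(nb, function(v) v[el[v] != "H"])
  donors <- which(el %in% c("N", "O", "S") & has_h)
  acceptors <- which((el == "O" & chg <= 0) |
                       (el == "N" & chg <= 0 &
                          lengths(nb) <= 3L))
  apolar <- which(el == "C" &
                    vapply(seq_along(el), function(i)
                      all(el[heavy_nb[[i]]] == "C"), TRUE))
  # charged groups: charged atom plus equivalent O partners (carboxylate)
  pos <- which(chg > 0)
  neg <- which(chg < 0)
  group_of <- function(i) {
    if (el[i] == "O") {
      # include sister oxygens on the same carbon (delocalized carboxylate)
      cc <- heavy_nb[[i]][el[heavy_nb[[i]]] == "C"]
      if (length(cc)) {
        sisters <- heavy_nb[[cc[1]]][el[heavy_nb[[cc[1]]]] == "O"]
        return(sort(unique(c(i, sisters))))
      }
    }
    i
  }
  list(donors = donors, acceptors = acceptors, apolar = apolar,
       cations = lapply(pos, group_of), anions = lapply(neg, group_of),
       rings = ligand_aromatic_rings(pose), nb = nb, has_h = has_h)
}

ligand_aromatic_rings <- function(pose) {
  hv <- which(pose$atoms$element != "H")
  if (length(hv) < 5L) return(list())
  remap <- match(seq_len(nrow(pose$atoms)), hv)
  b <- pose$bonds
  keep <- !is.na(remap[b$a1]) & !is.na(remap[b$a2])
  g <- anon_graph(length(hv), cbind(remap[b$a1[keep]], remap[b$a2[keep]]))
  rs <- tryCatch(sssr(g), error = function(e) list())
  arom <- pose$atoms$aromatic %||% rep(FALSE, nrow(pose$atoms))
  out <- list()
  for (r in rs) {
    orig <- hv[r]
    if (all(arom[orig])) out[[length(out) + 1L]] <- orig
  }
  out
}

# ---- protein typing -------------------------------------------------------

PROT_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  TRP = "NE1", ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1",
  TYR = "OH", CYS = "SG")
PROT_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"))
PROT_ROTATABLE <- c("OG", "OG1", "OH", "SG", "NZ")
PROT_RINGS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")))
PROT_ANIONS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
PROT_CATIONS <- list(ARG = c("NE", "NH1", "NH2", "CZ"), LYS = "NZ")

protein_typing <- function(rec) {
  at <- rec$atoms
  keys <- receptor_residue_keys(rec)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  heavy <- which(at$elesy != "H")
  hyd <- which(at$elesy == "H")
  # covalent adjacency among heavy atoms and H attachment, by distance
  h_parent <- integer(length(hyd))
  for (j in seq_along(hyd)) {
    d <- sqrt(colSums((t(xyz[heavy, , drop = FALSE]) - xyz[hyd[j], ])^2))
    h_parent[j] <- heavy[which.min(d)]
    if (min(d) > 1.3) h_parent[j] <- NA_integer_
  }
  donors <- list(); acceptors <- list(); apolar <- integer(0)
  rings <- list(); cations <- list(); anions <- list()
  for (key in unique(keys)) {
    sel <- which(keys == key)
    resid <- at$resid[sel[1]]
    name_of <- function(nm) sel[at$elety[sel] %in% nm]
    # backbone donor N (needs its H) and acceptor O
    nidx <- name_of("N")
    if (length(nidx)) {
      hs <- hyd[!is.na(h_parent) & h_parent == nidx[1]]
      if (length(hs)) {
        donors[[length(donors) + 1L]] <- list(idx = nidx[1], h = hs,
                                              rotatable = FALSE, key = key)
      }
    }
    oidx <- name_of("O")
    for (i in oidx) acceptors[[length(acceptors) + 1L]] <- list(idx = i, key = key)
    his_prot <- FALSE
    if (resid == "HIS") {
      nd <- name_of("ND1"); ne <- name_of("NE2")
      his_prot <- length(nd) && length(ne) &&
        any(!is.na(h_parent) & h_parent == nd[1]) &&
        any(!is.na(h_parent) & h_parent == ne[1])
    }
    dn <- PROT_DONORS[[resid]]
    for (nm in dn) {
      i <- name_of(nm)
      if (!length(i)) next
      hs <- hyd[!is.na(h_parent) & h_parent == i[1]]
      rot <- nm %in% PROT_ROTATABLE && !length(hs)
      if (length(hs) || rot) {
        donors[[length(donors) + 1L]] <- list(idx = i[1], h = hs,
                                              rotatable = rot, key = key)
      }
    }
    ac <- PROT_ACCEPTORS[[resid]]
    for (nm in ac) {
      i <- name_of(nm)
      if (!length(i)) next
      if (resid == "HIS") {
        # protonated imidazole nitrogens do not accept
        hs <- hyd[!is.na(h_parent) & h_parent == i[1]]
        if (length(hs)) next
      }
      acceptors[[length(acceptors) + 1L]] <- list(idx = i[1], key = key)
    }
    rg <- PROT_RINGS[[resid]]
    if (!is.null(rg)) {
      for (nm in rg) {
        i <- name_of(nm)
        if (length(i) == length(nm)) {
          rings[[length(rings) + 1L]] <- list(idx = i, key = key)
        }
      }
    }
    an <- PROT_ANIONS[[resid]]
    if (!is.null(an)) {
      i <- name_of(an)
      if (length(i)) anions[[length(anions) + 1L]] <- list(idx = i, key = key)
    }
    ct <- PROT_CATIONS[[resid]]
    if (!is.null(ct)) {
      i <- name_of(ct)
      if (length(i)) cations[[length(cations) + 1L]] <- list(idx = i, key = key)
    }
    if (resid == "HIS" && his_prot) {
      i <- name_of(c("ND1", "NE2", "CG", "CD2", "CE1"))
      cations[[length(cations) + 1L]] <- list(idx = i, key = key)
    }
  }
  # apolar carbons: all covalent heavy neighbors are carbon
  for (i in heavy) {
    if (at$elesy[i] != "C") next
    d <- sqrt(colSums((t(xyz[heavy, , drop = FALSE]) - xyz[i, ])^2))
    nbrs <- heavy[d > 1e-6 & d < 1.9]
    if (all(at$elesy[nbrs] == "C")) apolar <- c(apolar, i)
  }
  list(donors = donors, acceptors = acceptors, apolar = apolar,
       rings = rings, cations = cations, anions = anions,
       keys = keys, xyz = xyz, at = at)
}

prot_atom_id <- function(at, i) {
  paste0(residue_key(at$chain[i], at$resno[i], at$insert[i], at$resid[i]),
         ":", at$elety[i])
}

prot_group_id <- function(at, idx) {
  i <- idx[1]
  paste0(residue_key(at$chain[i], at$resno[i], at$insert[i], at$resid[i]),
         ":", paste(sort(at$elety[idx]), collapse = "+"))
}

# ---- detection ------------------------------------------------------------

#' Detect protein-ligand interactions for a docked pose
#'
#' Applies the geometric criteria of [default_cutoffs()] between an
#' explicit-hydrogen ligand pose and a receptor. Duplicate detections per
#' (kind, ligand atoms, protein atoms) keep only the shortest instance.
#'
#' @param pose a `mgvs_pose` (or a docking result carrying one as `$pose`).
#' @param rec a `mgvs_receptor`.
#' @param cutoffs cutoff list from [default_cutoffs()].
#' @return data.frame with columns `kind`, `lig_atoms` (comma-separated
#'   ligand atom indices), `prot_atoms` (protein atom/group id), `residue`
#'   (residue key), `distance`, `angle` (NA where undefined), `subtype`.
#' @export
detect_interactions <- function(pose, rec, cutoffs = default_cutoffs()) {
  if (!is.null(pose$pose)) pose <- pose$pose
  stopifnot(inherits(pose, "mgvs_pose"), inherits(rec, "mgvs_receptor"))
  lt <- ligand_typing(pose)
  pt <- protein_typing(rec)
  lxyz <- pose_coords(pose)
  at <- pt$at
  rows <- list()
  emit <- function(kind, lig, prot, residue, distance, angle = NA_real_,
                   subtype = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, lig_atoms = paste(sort(lig), collapse = ","),
      prot_atoms = prot, residue = residue, distance = distance,
      angle = angle, subtype = subtype, stringsAsFactors = FALSE)
  }

  # hydrogen bonds: ligand donor -> protein acceptor
  for (d in lt$donors) {
    hs <- lt$nb[[d]][pose$atoms$element[lt$nb[[d]]] == "H"]
    for (a in pt$acceptors) {
      A <- pt$xyz[a$idx, ]
      dd <- vdist(lxyz[d, ], A)
      if (dd > cutoffs$hbond_dist) next
      ang <- max(vapply(hs, function(h)
        dha_angle(lxyz[d, ], lxyz[h, ], A), 1.0))
      if (ang >= cutoffs$hbond_angle) {
        emit("hbond", d, prot_atom_id(at, a$idx), a$key, dd, ang,
             "lig_donor")
      }
    }
  }
  # hydrogen bonds: protein donor -> ligand acceptor
  for (d in pt$donors) {
    D <- pt$xyz[d$idx, ]
    for (a in lt$acceptors) {
      A <- lxyz[a, ]
      dd <- vdist(D, A)
      if (dd > cutoffs$hbond_dist) next
      if (length(d$h)) {
        ang <- max(vapply(d$h, function(h) dha_angle(D, pt$xyz[h, ], A), 1.0))
      } else if (d$rotatable) {
        ante <- antecedent_of(pt, d$idx)
        if (is.na(ante)) next
        ang <- rotatable_dha(D, pt$xyz[ante, ], A)
      } else next
      if (ang >= cutoffs$hbond_angle) {
        emit("hbond", a, prot_atom_id(at, d$idx), d$key, dd, ang,
             "prot_donor")
      }
    }
  }
  # hydrophobic contacts
  for (i in lt$apolar) {
    for (j in pt$apolar) {
      dd <- vdist(lxyz[i, ], pt$xyz[j, ])
      if (dd <= cutoffs$hydrophobic_dist) {
        emit("hydrophobic", i, prot_atom_id(at, j), pt$keys[j], dd)
      }
    }
  }
  # salt bridges
  salt <- function(lgroups, pgroups) {
    for (lg in lgroups) {
      lc <- colMeans(lxyz[lg, , drop = FALSE])
      for (pg in pgroups) {
        pc <- colMeans(pt$xyz[pg$idx, , drop = FALSE])
        dd <- vdist(lc, pc)
        if (dd <= cutoffs$salt_dist) {
          emit("salt_bridge", lg, prot_group_id(at, pg$idx), pg$key, dd)
        }
      }
    }
  }
  salt(lt$cations, pt$anions)
  salt(lt$anions, pt$cations)
  # pi-stacking
  for (lr in lt$rings) {
    lp <- ring_plane(lxyz[lr, , drop = FALSE])
    for (pr in pt$rings) {
      pp <- ring_plane(pt$xyz[pr$idx, , drop = FALSE])
      dd <- vdist(lp$center, pp$center)
      pa <- plane_angle(lp$normal, pp$normal)
      off <- ring_offset(lp, pp)
      if (off > cutoffs$pistack_offset) next
      sub <- NULL
      if (dd <= cutoffs$pistack_parallel_dist &&
          pa <= cutoffs$pistack_parallel_angle) {
        sub <- "parallel"
      } else if (dd <= cutoffs$pistack_perp_dist &&
                 pa >= cutoffs$pistack_perp_angle[1] &&
                 pa <= cutoffs$pistack_perp_angle[2]) {
        sub <- "perpendicular"
      }
      if (!is.null(sub)) {
        emit("pi_stack", lr, prot_group_id(at, pr$idx), pr$key, dd, pa, sub)
      }
    }
  }
  # pi-cation: protein ring vs ligand cation, ligand ring vs protein cation
  for (lg in lt$cations) {
    lc <- colMeans(lxyz[lg, , drop = FALSE])
    for (pr in pt$rings) {
      pp <- ring_plane(pt$xyz[pr$idx, , drop = FALSE])
      dd <- vdist(lc, pp$center)
      if (dd <= cutoffs$pication_dist) {
        emit("pi_cation", lg, prot_group_id(at, pr$idx), pr$key, dd)
      }
    }
  }
  for (lr in lt$rings) {
    lp <- ring_plane(lxyz[lr, , drop = FALSE])
    for (pg in pt$cations) {
      pc <- colMeans(pt$xyz[pg$idx, , drop = FALSE])
      dd <- vdist(lp$center, pc)
      if (dd <= cutoffs$pication_dist) {
        emit("pi_cation", lr, prot_group_id(at, pg$idx), pg$key, dd)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(kind = character(0), lig_atoms = character(0),
                      prot_atoms = character(0), residue = character(0),
                      distance = numeric(0), angle = numeric(0),
                      subtype = character(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  # atoms of stacked rings make trivial carbon-carbon contacts; suppress
  # hydrophobic records already explained by a detected pi-stack
  st <- df[df$kind == "pi_stack", , drop = FALSE]
  if (nrow(st) && any(df$kind == "hydrophobic")) {
    drop <- logical(nrow(df))
    for (s in seq_len(nrow(st))) {
      lig_ring <- strsplit(st$lig_atoms[s], ",")[[1]]
      drop <- drop | (df$kind == "hydrophobic" &
                        df$lig_atoms %in% lig_ring &
                        df$residue == st$residue[s])
    }
    df <- df[!drop, , drop = FALSE]
  }
  # dedup: shortest instance per (kind, ligand atoms, protein atoms)
  df <- df[order(df$kind, df$lig_atoms, df$prot_atoms, df$distance), ,
           drop = FALSE]
  df <- df[!duplicated(df[, c("kind", "lig_atoms", "prot_atoms")]), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

antecedent_of <- function(pt, idx) {
  # nearest covalently bonded heavy atom
  heavy <- which(pt$at$elesy != "H")
  d <- sqrt(colSums((t(pt$xyz[heavy, , drop = FALSE]) - pt$xyz[idx, ])^2))
  cand <- heavy[d > 1e-6 & d < 1.9]
  if (!length(cand)) return(NA_integer_)
  cand[which.min(d[match(cand, heavy)])]
}

# ---- matching -------------------------------------------------------------

#' Match interactions of a hit pose against a query pose
#'
#' A query interaction is matched when some hit interaction has the same
#' kind and the same protein partner: the identical protein atom (or
#' atom group) at `level = "atom"`, or merely the same residue at
#' `level = "residue"`. `scope = "specific"` first restricts both sides to
#' the directed, non-hydrophobic kinds (hydrogen bonds, salt bridges and pi
#' interactions).
#'
#' @param query_ints,hit_ints interaction tables from
#'   [detect_interactions()] against the same receptor.
#' @param level `"atom"` or `"residue"`.
#' @param scope `"all"` or `"specific"`.
#' @return list of class `mgvs_match`: `level`, `scope`, `n_query`,
#'   `shared`, `all_shared`, `any_shared`, `per_kind` (data.frame).
#' @export
match_interactions <- function(query_ints, hit_ints,
                               level = c("atom", "residue"),
                               scope = c("all", "specific")) {
  level <- match.arg(level)
  scope <- match.arg(scope)
  if (scope == "specific") {
    query_ints <- query_ints[query_ints$kind %in% SPECIFIC_KINDS, , drop = FALSE]
    hit_ints <- hit_ints[hit_ints$kind %in% SPECIFIC_KINDS, , drop = FALSE]
  }
  tag <- function(df) {
    if (level == "atom") paste(df$kind, df$prot_atoms)
    else paste(df$kind, df$residue)
  }
  qtags <- unique(tag(query_ints))
  htags <- unique(tag(hit_ints))
  matched <- qtags %in% htags
  per_kind <- NULL
  if (length(qtags)) {
    kind_of <- sub(" .*$", "", qtags)
    per_kind <- stats::aggregate(matched, by = list(kind = kind_of),
                                 FUN = function(v) c(n = length(v), shared = sum(v)))
    per_kind <- data.frame(kind = per_kind$kind,
                           n_query = per_kind$x[, "n"],
                           shared = per_kind$x[, "shared"])
  } else {
    per_kind <- data.frame(kind = character(0), n_query = integer(0),
                           shared = integer(0))
  }
  structure(list(level = level, scope = scope,
                 n_query = length(qtags), shared = sum(matched),
                 all_shared = length(qtags) > 0 && all(matched),
                 any_shared = any(matched), per_kind = per_kind),
            class = "mgvs_match")
}

#' @export
print.mgvs_match <- function(x, ...) {
  cat(sprintf("<match %s/%s: %d/%d query interactions shared (all=%s, any=%s)>\n",
              x$level, x$scope, x$shared, x$n_query, x$all_shared, x$any_shared))
  invisible(x)
}

#' Shared-interaction proportion tables
#'
#' Summarizes, over a set of queries each with a list of hit interaction
#' tables, the proportion of hits sharing all (and at least one) query
#' interactions — overall, per interaction kind, and per query. The per-kind
#' table counts, for each kind, only hits whose query makes that kind of
#' interaction (its `n`).
#'
#' @param queries list of entries, each `list(query = <interaction table>,
#'   hits = list(<interaction table>, ...))`.
#' @param level `"atom"` or `"residue"`.
#' @param scope `"all"` or `"specific"`.
#' @return list: `per_kind` (kind, n, prop_all, prop_any), `overall`
#'   (prop_all, prop_any, n), `per_query` (fraction of queries with >= 1 hit
#'   sharing all / at least one interaction).
#' @export
shared_interaction_stats <- function(queries, level = c("atom", "residue"),
                                     scope = c("all", "specific")) {
  level <- match.arg(level)
  scope <- match.arg(scope)
  if (!length(queries) || !all(vapply(queries, function(q)
    length(q$hits) > 0, TRUE))) {
    abort_mgvs("need at least one query, each with at least one hit",
               "mgvs_argument_error")
  }
  kind_rows <- list()
  overall_all <- c(); overall_any <- c()
  q_all <- logical(length(queries)); q_any <- logical(length(queries))
  for (qi in seq_along(queries)) {
    q <- queries[[qi]]
    summaries <- lapply(q$hits, function(h)
      match_interactions(q$query, h, level, scope))
    overall_all <- c(overall_all, vapply(summaries, `[[`, TRUE, "all_shared"))
    overall_any <- c(overall_any, vapply(summaries, `[[`, TRUE, "any_shared"))
    q_all[qi] <- any(vapply(summaries, `[[`, TRUE, "all_shared"))
    q_any[qi] <- any(vapply(summaries, `[[`, TRUE, "any_shared"))
    for (s in summaries) {
      pk <- s$per_kind
      if (nrow(pk)) {
        pk$all_match <- pk$shared == pk$n_query
        pk$any_match <- pk$shared > 0
        kind_rows[[length(kind_rows) + 1L]] <- pk
      }
    }
  }
  per_kind <- data.frame(kind = character(0), n = integer(0),
                         prop_all = numeric(0), prop_any = numeric(0))
  if (length(kind_rows)) {
    all_pk <- do.call(rbind, kind_rows)
    agg <- stats::aggregate(cbind(all_match, any_match) ~ kind, all_pk, mean)
    cnt <- stats::aggregate(n_query ~ kind, all_pk, length)
    per_kind <- data.frame(kind = agg$kind, n = cnt$n_query,
                           prop_all = agg$all_match, prop_any = agg$any_match)
  }
  list(per_kind = per_kind,
       overall = list(prop_all = mean(overall_all),
                      prop_any = mean(overall_any),
                      n = length(overall_all)),
       per_query = list(frac_all = mean(q_all), frac_any = mean(q_any),
                        n = length(queries)))
}
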
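# Three-part compound filter: irregular-structure rules (cumulated double
# bonds; ring sizes other than 5/6; overly large or looped fused ring
# systems), PAINS substructure alerts, and configurable drug-likeness
# property ranges. Pure graph/substructure tests; no geometry is computed.

#' Default filter configuration
#'
#' Structural rules on, the bundled PAINS catalog, and drug-like ranges of
#' MW 150-500 Da, logP <= 5, HBD <= 5, HBA <= 10, rotatable bonds <= 10.
#' Every rule can be disabled and every range overridden.
#'
#' @return list understood by [apply_filter_stack()].
#' @export
default_filter_config <- function() {
  list(
    cumulated_double_bond = TRUE,
    ring_rules = TRUE,
    allowed_ring_sizes = c(5L, 6L),
    max_fused_rings = 4L,
    pains = TRUE,
    pains_catalog = system.file("extdata", "pains_subset.smarts",
                                package = "mgvs", mustWork = TRUE),
    properties = TRUE,
    ranges = list(mw = c(150, 500), logp = c(-Inf, 5), hbd = c(0, 5),
                  hba = c(0, 10), rot_bonds = c(0, 10))
  )
}

#' Read a filter configuration from YAML
#'
#' Unspecified fields fall back to [default_filter_config()]. Ranges are
#' two-element `[min, max]` lists; `.inf`/`-.inf` are honored.
#'
#' @param path YAML file.
#' @return filter config list.
#' @export
read_filter_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_filter_config()
  for (k in names(user)) {
    if (k == "ranges") {
      for (p in names(user$ranges)) cfg$ranges[[p]] <- as.numeric(user$ranges[[p]])
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  cfg
}

#' Cumulated double bond check
#'
#' Flags allene-like arrangements: an atom carrying two or more non-aromatic
#' double bonds. Conjugated systems (alternating single/double) and aromatic
#' rings never trigger — the rule targets strained cumulated geometries, not
#' conjugation.
#'
#' @param mol a `mgvs_mol`.
#' @return `NULL` if clean, otherwise a violation record (list with `rule`,
#'   `detail`).
#' @export
cumulated_double_bond_check <- function(mol) {
  stopifnot(inherits(mol, "mgvs_mol"))
  b <- mol$bonds
  dbl <- b[b$order == 2L & !b$aromatic, , drop = FALSE]
  if (nrow(dbl) < 2L) return(NULL)
  cnt <- tabulate(c(dbl$a1, dbl$a2), nrow(mol$atoms))
  bad <- which(cnt >= 2L)
  if (!length(bad)) return(NULL)
  list(rule = "cumulated_double_bond",
       detail = sprintf("atom(s) %s carry %s non-aromatic double bonds",
                        paste(bad, collapse = ","),
                        paste(cnt[bad], collapse = ",")))
}

#' Ring system check
#'
#' Emits one violation per offense: (a) `ring_size` for any smallest-ring
#' size outside the allowed set (default 5/6); (b) `fused_count` for a fused
#' system of more than `max_fused` rings; (c) `ring_loop` for a fused system
#' whose ring-adjacency graph contains a cycle (bridged or cage-like
#' polycyclics such as adamantane).
#'
#' @param mol a `mgvs_mol`.
#' @param allowed_sizes allowed smallest-ring sizes.
#' @param max_fused maximum rings per fused system.
#' @return list of violation records (empty if clean).
#' @export
ring_system_check <- function(mol, allowed_sizes = c(5L, 6L), max_fused = 4L) {
  stopifnot(inherits(mol, "mgvs_mol"))
  rs <- sssr(mol)
  out <- list()
  sizes <- lengths(rs)
  off <- which(!(sizes %in% allowed_sizes))
  for (i in off) {
    out[[length(out) + 1L]] <- list(
      rule = "ring_size",
      detail = sprintf("%d-membered ring (allowed: %s)", sizes[[i]],
                       paste(allowed_sizes, collapse = ",")))
  }
  if (length(rs) >= 2L) {
    fused <- fused_ring_systems(rs)
    adj <- fused$adjacency
    for (sys in fused$systems) {
      if (length(sys) > max_fused) {
        out[[length(out) + 1L]] <- list(
          rule = "fused_count",
          detail = sprintf("fused system of %d rings (max %d)", length(sys),
                           max_fused))
      }
      if (length(sys) >= 2L) {
        inside <- adj[adj[, 1] %in% sys & adj[, 2] %in% sys, , drop = FALSE]
        if (nrow(inside) > length(sys) - 1L) {
          out[[length(out) + 1L]] <- list(
            rule = "ring_loop",
            detail = sprintf("ring-adjacency graph of %d-ring system contains a cycle",
                             length(sys)))
        }
      }
    }
  }
  out
}

#' PAINS substructure check
#'
#' Matches the molecule against a pan-assay interference SMARTS catalog and
#' returns the names of every matching pattern; an empty vector is a pass.
#'
#' @param mol a `mgvs_mol`.
#' @param catalog data.frame (`smarts`, `name`) or a catalog file path.
#' @return character vector of matched pattern names.
#' @export
pains_check <- function(mol, catalog = NULL) {
  stopifnot(inherits(mol, "mgvs_mol"))
  if (is.null(catalog)) catalog <- default_filter_config()$pains_catalog
  if (is.character(catalog)) catalog <- load_smarts_catalog(catalog)
  if (!nrow(catalog)) return(character(0))
  hit <- vapply(catalog$smarts,
                function(s) smarts_count(mol$smiles, s) > 0L, TRUE)
  catalog$name[hit]
}

#' Drug-likeness range check
#'
#' One violation per property outside its configured `[min, max]` range.
#'
#' @param mol a `mgvs_mol`.
#' @param ranges named list of two-element numeric ranges over
#'   `mgvs_props` fields; defaults from [default_filter_config()].
#' @param props optional precomputed `mgvs_props` (avoids recomputation).
#' @return list of violation records.
#' @export
drug_like_check <- function(mol, ranges = NULL, props = NULL) {
  stopifnot(inherits(mol, "mgvs_mol"))
  if (is.null(ranges)) ranges <- default_filter_config()$ranges
  for (p in names(ranges)) {
    r <- ranges[[p]]
    if (length(r) != 2L || r[1] > r[2]) {
      abort_mgvs(sprintf("inverted or malformed range for property '%s'", p),
                 "mgvs_config_error")
    }
  }
  if (is.null(props)) props <- compute_properties(mol)
  out <- list()
  for (p in names(ranges)) {
    v <- props[[p]]
    if (is.null(v)) {
      abort_mgvs(sprintf("unknown property '%s' in range config", p),
                 "mgvs_config_error")
    }
    r <- ranges[[p]]
    if (v < r[1] || v > r[2]) {
      out[[length(out) + 1L]] <- list(
        rule = paste0("property:", p),
        detail = sprintf("%s=%.4g outside [%.4g, %.4g]", p, v, r[1], r[2]))
    }
  }
  out
}

#' Apply the full filter stack
#'
#' Runs every enabled sub-filter on each molecule. A molecule survives iff
#' all enabled rules pass; input order is preserved among survivors and a
#' report is emitted for every input.
#'
#' @param mols list of `mgvs_mol`.
#' @param config filter configuration (see [default_filter_config()]).
#' @return list with `survivors` (list of `mgvs_mol`) and `reports`
#'   (data.frame: `id`, `passed`, `failures` — rule names collapsed with
#'   `";"` — and `details`).
#' @export
apply_filter_stack <- function(mols, config = default_filter_config()) {
  catalog <- NULL
  if (isTRUE(config$pains)) {
    catalog <- load_smarts_catalog(config$pains_catalog)
  }
  reports <- vector("list", length(mols))
  keep <- logical(length(mols))
  for (i in seq_along(mols)) {
    m <- mols[[i]]
    fails <- list()
    if (isTRUE(config$cumulated_double_bond)) {
      v <- cumulated_double_bond_check(m)
      if (!is.null(v)) fails[[length(fails) + 1L]] <- v
    }
    if (isTRUE(config$ring_rules)) {
      fails <- c(fails, ring_system_check(m, config$allowed_ring_sizes,
                                          config$max_fused_rings))
    }
    if (isTRUE(config$pains)) {
      hits <- pains_check(m, catalog)
      for (h in hits) {
        fails[[length(fails) + 1L]] <- list(rule = "pains",
                                            detail = h)
      }
    }
    if (isTRUE(config$properties)) {
      fails <- c(fails, drug_like_check(m, config$ranges))
    }
    keep[i] <- length(fails) == 0L
    reports[[i]] <- data.frame(
      id = m$id, passed = keep[i],
      failures = paste(vapply(fails, `[[`, "", "rule"), collapse = ";"),
      details = paste(vapply(fails, `[[`, "", "detail"), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  list(survivors = mols[keep], reports = do.call(rbind, reports) %||%
         data.frame(id = character(0), passed = logical(0),
                    failures = character(0), details = character(0)))
}
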
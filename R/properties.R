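# Molecular properties used by the filter stack and the evaluation tables.
# Bulk descriptors (MW, logP, H-bond counts, TPSA) come from OpenBabel;
# drug-likeness (QED) is computed from the published desirability-function
# parameterization over eight descriptors; synthetic accessibility is a
# self-contained graph-complexity heuristic mapped to [1, 10] (lower =
# easier), since no fragment-contribution database ships with this package.

ROTATABLE_SMARTS <- "[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]"

# Asymmetric double-sigmoid desirability parameters (a, b, c, d, e, f, dmax)
# for the eight QED descriptors, and the consensus weights.
QED_ADS <- list(
  mw     = c(2.817065973, 392.5754953, 290.7489764, 2.419764353, 49.22325677, 65.37051707, 104.98055614),
  alogp  = c(3.172690585, 137.8624751, 2.534937431, 4.581497897, 0.822739154, 0.576295591, 131.31866035),
  hba    = c(2.948620388, 160.4605972, 3.615294657, 4.435986202, 0.290141953, 1.300669958, 148.77630464),
  hbd    = c(1.618662227, 1010.051101, 0.985094388, 0.000000001, 0.713820843, 0.920922555, 258.16326158),
  psa    = c(1.876861559, 125.2232657, 62.90773554, 87.83366614, 12.01999824, 28.51324732, 104.56861672),
  rotb   = c(0.010000000, 272.4121427, 2.558379970, 1.565547684, 1.271567166, 2.758063707, 105.44204028),
  arom   = c(3.217788970, 957.7374108, 2.274627939, 0.000000001, 1.317690384, 0.375760881, 312.33726097),
  alerts = c(0.010000000, 1199.094025, -0.09002883, 0.000000001, 0.185904477, 0.875193782, 417.72531400))
QED_WEIGHTS <- c(mw = 0.66, alogp = 0.46, hba = 0.05, hbd = 0.61,
                 psa = 0.06, rotb = 0.65, arom = 0.48, alerts = 0.95)

qed_ads <- function(x, p) {
  v <- p[1] + p[2] / (1 + exp(-(x - p[3] + p[4] / 2) / p[5])) *
    (1 - 1 / (1 + exp(-(x - p[3] - p[4] / 2) / p[6])))
  max(v / p[7], 1e-6)
}

smarts_count <- function(smiles, smarts) {
  res <- ChemmineOB::forEachMol("SMILES", smiles, function(m) {
    ChemmineOB::smartsSearch_OB(list(m), smarts)
  })
  as.integer(res[[1]])
}

load_smarts_catalog <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad)) {
    abort_mgvs(sprintf("malformed SMARTS catalog entry at %s line(s) %s",
                       path, paste(bad, collapse = ", ")),
               "mgvs_config_error")
  }
  df <- data.frame(smarts = vapply(fields, `[[`, "", 1L),
                   name = vapply(fields, `[[`, "", 2L),
                   stringsAsFactors = FALSE)
  # validate patterns once at load time
  probe <- ChemmineOB::forEachMol("SMILES", "CCO", function(m) {
    vapply(df$smarts, function(s) {
      tryCatch({ChemmineOB::smartsSearch_OB(list(m), s); TRUE},
               error = function(e) FALSE)
    }, TRUE)
  })[[1]]
  if (!all(probe)) {
    abort_mgvs(sprintf("invalid SMARTS in catalog %s: %s", path,
                       paste(df$name[!probe], collapse = ", ")),
               "mgvs_config_error")
  }
  df
}

default_alert_catalog <- function() {
  load_smarts_catalog(system.file("extdata", "structural_alerts.smarts",
                                  package = "mgvs", mustWork = TRUE))
}

count_aromatic_rings <- function(mol) {
  rs <- sssr(mol)
  if (!length(rs)) return(0L)
  sum(vapply(rs, function(r) all(mol$atoms$aromatic[r]), TRUE))
}

#' Compute the property record of a molecule
#'
#' Reports molecular weight, heavy-atom count, drug-likeness (QED, in
#' `[0, 1]`, higher = more drug-like), synthetic accessibility (SA, in
#' `[1, 10]`, lower = easier), logP, H-bond donor/acceptor counts and
#' rotatable bonds. Deterministic: repeated calls are bit-identical.
#'
#' @param mol a `mgvs_mol`.
#' @param alerts optional structural-alert catalog (data.frame with `smarts`,
#'   `name`) used by the QED alerts term; the bundled catalog by default.
#' @return list of class `mgvs_props` with fields `mw`, `heavy_atoms`, `qed`,
#'   `sa`, `logp`, `hbd`, `hba`, `rot_bonds`, `tpsa`, `aromatic_rings`,
#'   `alerts`.
#' @export
compute_properties <- function(mol, alerts = NULL) {
  stopifnot(inherits(mol, "mgvs_mol"))
  if (is.null(alerts)) alerts <- default_alert_catalog()
  sdf <- ChemmineR::smiles2sdf(stats::setNames(mol$smiles, mol$id))
  pr <- ChemmineR::propOB(sdf)
  rotb <- smarts_count(mol$smiles, ROTATABLE_SMARTS)
  n_alerts <- sum(vapply(alerts$smarts,
                         function(s) smarts_count(mol$smiles, s) > 0L, TRUE))
  arom <- count_aromatic_rings(mol)
  desc <- c(mw = as.numeric(pr$MW), alogp = as.numeric(pr$logP),
            hba = as.numeric(pr$HBA1), hbd = as.numeric(pr$HBD),
            psa = as.numeric(pr$TPSA), rotb = rotb, arom = arom,
            alerts = n_alerts)
  d <- vapply(names(QED_ADS), function(k) qed_ads(desc[[k]], QED_ADS[[k]]),
              1.0)
  qed <- exp(sum(QED_WEIGHTS * log(d)) / sum(QED_WEIGHTS))
  structure(list(
    mw = as.numeric(pr$MW), heavy_atoms = n_heavy_atoms(mol),
    qed = qed, sa = sa_score(mol), logp = as.numeric(pr$logP),
    hbd = as.integer(pr$HBD), hba = as.integer(pr$HBA1),
    rot_bonds = rotb, tpsa = as.numeric(pr$TPSA),
    aromatic_rings = arom, alerts = n_alerts), class = "mgvs_props")
}

#' @export
print.mgvs_props <- function(x, ...) {
  cat(sprintf(paste0("mw=%.1f heavy=%d qed=%.3f sa=%.2f logp=%.2f ",
                     "hbd=%d hba=%d rotb=%d\n"),
              x$mw, x$heavy_atoms, x$qed, x$sa, x$logp, x$hbd, x$hba,
              x$rot_bonds))
  invisible(x)
}

#' Synthetic accessibility heuristic
#'
#' Graph-complexity estimate in `[1, 10]` (lower = easier to make). Penalizes
#' size, ring count, macrocycles, bridged/caged and spiro ring systems, and
#' unusual heteroatom density; rewards repeated atom environments. It is a
#' coarse stand-alone heuristic intended for relative ranking of desk-scale
#' sets, not a trained fragment-contribution model.
#'
#' @param mol a `mgvs_mol`.
#' @return numeric in `[1, 10]`.
#' @export
sa_score <- function(mol) {
  stopifnot(inherits(mol, "mgvs_mol"))
  heavy <- n_heavy_atoms(mol)
  rs <- sssr(mol)
  fused <- fused_ring_systems(rs)
  n_macro <- sum(lengths(rs) > 8L)
  # bridged/caged: cycle in the ring-adjacency graph of a fused system
  bridged <- 0L
  spiro <- 0L
  if (length(rs) >= 2L) {
    adj <- fused$adjacency
    for (sys in fused$systems) {
      if (length(sys) < 2L) next
      inside <- adj[adj[, 1] %in% sys & adj[, 2] %in% sys, , drop = FALSE]
      if (nrow(inside) > length(sys) - 1L) bridged <- bridged + 1L
    }
    if (nrow(adj)) {
      shared1 <- vapply(seq_len(nrow(adj)), function(i) {
        length(intersect(rs[[adj[i, 1]]], rs[[adj[i, 2]]])) == 1L
      }, TRUE)
      spiro <- sum(shared1)
    }
  }
  env <- paste(mol$atoms$element, mol$atoms$charge, mol$atoms$aromatic,
               tabulate(c(mol$bonds$a1, mol$bonds$a2), heavy))
  repetition <- 1 - length(unique(env)) / heavy
  hetero_frac <- mean(!(mol$atoms$element %in% c("C", "H")))
  raw <- 1 +
    0.7 * log1p(max(0, heavy - 20)) +
    0.25 * length(rs) +
    1.2 * bridged +
    0.6 * spiro +
    1.0 * n_macro +
    3.0 * max(0, hetero_frac - 0.5) -
    1.5 * repetition
  min(10, max(1, raw))
}
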
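# Docking engine adapters and score metrics.
#
# The engine contract is deliberately thin: an engine is a list with a `tag`
# and a `score(mol, pose, rec)` function returning a Vina-scale affinity in
# kcal/mol (more negative = better). Two adapters are provided: the
# deterministic mock engine (see synthetic fixtures) and an external
# Vina-family executable driven through PDBQT files, whose output is parsed
# at the text level so QuickVina2 and AutoDock Vina are interchangeable.

#' External Vina-family engine adapter
#'
#' Prepares receptor/ligand PDBQT via OpenBabel, invokes the executable with
#' the receptor's box, and parses the best-mode affinity from the standard
#' result table.
#'
#' @param path path to the vina/qvina executable.
#' @return engine adapter list.
#' @export
vina_engine <- function(path) {
  if (!nzchar(Sys.which(path)) && !file.exists(path)) {
    abort_mgvs(sprintf("docking executable not found: %s", path),
               "mgvs_config_error")
  }
  structure(list(
    tag = paste0("exe:", basename(path)),
    score = function(mol, pose, rec) {
      rec_q <- tempfile(fileext = ".pdbqt")
      lig_q <- tempfile(fileext = ".pdbqt")
      out_q <- tempfile(fileext = ".pdbqt")
      rec_pdb <- tempfile(fileext = ".pdb")
      on.exit(unlink(c(rec_q, lig_q, out_q, rec_pdb)))
      writeLines(receptor_pdb_text(rec), rec_pdb)
      run_obabel(c(rec_pdb, "-opdbqt", "-xr", "-O", rec_q))
      lig_sdf <- tempfile(fileext = ".sdf")
      writeLines(pose_to_sdf_text(pose), lig_sdf)
      run_obabel(c(lig_sdf, "-opdbqt", "-O", lig_q))
      unlink(lig_sdf)
      args <- c("--receptor", rec_q, "--ligand", lig_q, "--out", out_q,
                "--center_x", rec$box_center[1], "--center_y", rec$box_center[2],
                "--center_z", rec$box_center[3],
                "--size_x", rec$box_edge, "--size_y", rec$box_edge,
                "--size_z", rec$box_edge)
      res <- tryCatch(
        system2(path, args, stdout = TRUE, stderr = TRUE),
        error = function(e) abort_mgvs(
          sprintf("engine invocation failed for '%s': %s", mol$id,
                  conditionMessage(e)), "mgvs_engine_error"))
      parse_vina_output(paste(res, collapse = "\n"), mol$id)
    }), class = "mgvs_engine")
}

#' Parse the result table of a Vina-family program
#'
#' Accepts the standard `mode | affinity | ...` table or
#' `REMARK VINA RESULT` lines and returns the best-mode affinity.
#'
#' @param text captured stdout of the engine.
#' @param id molecule id for error messages.
#' @return numeric affinity (kcal/mol).
#' @export
parse_vina_output <- function(text, id = "?") {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  rem <- grep("^REMARK VINA RESULT:", lines, value = TRUE)
  if (length(rem)) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(
      sub("^REMARK VINA RESULT:", "", rem[[1]])), "[ ]+")[[1]][1]))
    if (!is.na(v)) return(v)
  }
  tab <- grep("^\\s*1\\s+-?[0-9]+\\.[0-9]", lines, value = TRUE)
  if (length(tab)) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(tab[[1]]), "[ ]+")[[1]][2]))
    if (!is.na(v)) return(v)
  }
  abort_mgvs(sprintf("cannot parse engine output for molecule '%s'", id),
             "mgvs_engine_error")
}

receptor_pdb_text <- function(rec) {
  at <- rec$atoms
  nm4 <- ifelse(nchar(at$elety) < 4, sprintf(" %-3s", at$elety), at$elety)
  vapply(seq_len(nrow(at)), function(i) {
    sprintf("ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, nm4[i], at$resid[i], at$chain[i], at$resno[i],
            ifelse(nzchar(at$insert[i]), at$insert[i], " "),
            at$x[i], at$y[i], at$z[i], at$elesy[i])
  }, "")
}

#' Score the conformers of a molecule against a receptor
#'
#' One docking result per conformer. The mock engine scores from the
#' molecular identity and pose position (deterministic); an external engine
#' runs the full file-preparation + invocation + parse path.
#'
#' @param cs `mgvs_conformers`.
#' @param rec `mgvs_receptor`.
#' @param engine an engine adapter (see [vina_engine()] and [mock_engine()]).
#' @return list of `mgvs_docking_result`: `id`, `conformer`, `pose`, `vina`,
#'   `vina_eff`, `engine`.
#' @export
score_pose <- function(cs, rec, engine) {
  stopifnot(inherits(cs, "mgvs_conformers"), inherits(rec, "mgvs_receptor"),
            inherits(engine, "mgvs_engine"))
  heavy <- n_heavy_atoms(cs$mol)
  lapply(seq_along(cs$conformers), function(i) {
    pose <- cs$conformers[[i]]
    v <- engine$score(cs$mol, pose, rec)
    structure(list(id = cs$id, conformer = i, pose = pose, vina = v,
                   vina_eff = vina_efficiency(v, heavy), engine = engine$tag),
              class = "mgvs_docking_result")
  })
}

#' @export
print.mgvs_docking_result <- function(x, ...) {
  cat(sprintf("<dock %s[%d]: vina=%.2f eff=%.3f (%s)>\n", x$id, x$conformer,
              x$vina, x$vina_eff, x$engine))
  invisible(x)
}

#' Best docking result of a set
#'
#' Minimum Vina score; ties broken by lower conformer index.
#'
#' @param results non-empty list of docking results.
#' @return the best `mgvs_docking_result`.
#' @export
best_result <- function(results) {
  if (!length(results)) {
    abort_mgvs("best_result called on an empty result list",
               "mgvs_argument_error")
  }
  vs <- vapply(results, function(r) as.numeric(r$vina), 1.0)
  ks <- vapply(results, function(r) as.numeric(r$conformer), 1.0)
  results[[order(vs, ks)[1]]]
}

#' Vina efficiency (ligand efficiency)
#'
#' Vina score divided by the heavy-atom count; corrects the size bias of the
#' raw score so differently sized compounds can be ranked together.
#'
#' @param vina Vina score, kcal/mol.
#' @param heavy_atoms heavy-atom count (>= 1).
#' @return kcal/mol per heavy atom.
#' @export
vina_efficiency <- function(vina, heavy_atoms) {
  if (any(heavy_atoms < 1)) {
    abort_mgvs("heavy_atoms must be >= 1", "mgvs_argument_error")
  }
  vina / heavy_atoms
}

#' Score difference against a reference ligand
#'
#' `hit - reference`; negative means the hit scores better. The reference is
#' typically the query compound or the crystal ligand.
#'
#' @param hit_vina,ref_vina Vina scores, kcal/mol.
#' @return kcal/mol.
#' @export
delta_vina <- function(hit_vina, ref_vina) hit_vina - ref_vina
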
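# Receptor structures: PDB parsing (via bio3d), protein-chain extraction,
# element inference, docking-box bookkeeping, and idealized placement of the
# polar hydrogens that the hydrogen-bond angle criterion needs.

#' Read a receptor structure from PDB text or file
#'
#' Retains protein `ATOM` records only (waters and hetero ligands are
#' dropped), keeps alternate location "A"/blank, infers the element from the
#' atom name when the element column is empty, and records the docking box.
#' Backbone amide hydrogens are placed with idealized geometry when the
#' input carries no hydrogens; rotatable polar hydrogens (hydroxyls, lysine
#' ammonium) are handled analytically at interaction-detection time.
#'
#' @param pdb PDB file path, or PDB-format text (detected by newline).
#' @param box_center numeric xyz (Angstrom) of the docking box center.
#' @param box_edge box edge length in Angstrom (default 20).
#' @param id receptor identifier tag.
#' @return A `mgvs_receptor`: list with `atoms` (data.frame: `chain`,
#'   `resno`, `insert`, `resid`, `elety`, `elesy`, `x`, `y`, `z`),
#'   `box_center`, `box_edge`, `id`.
#' @export
read_receptor <- function(pdb, box_center = c(0, 0, 0), box_edge = 20,
                          id = "receptor") {
  if (box_edge <= 0) {
    abort_mgvs("box_edge must be positive", "mgvs_argument_error")
  }
  path <- pdb
  if (grepl("\n", pdb, fixed = TRUE) || !file.exists(pdb)) {
    if (!grepl("^(ATOM|HETATM|HEADER|REMARK|MODEL|CRYST)", pdb)) {
      abort_mgvs("input is neither an existing file nor PDB-format text",
                 "mgvs_format_error")
    }
    path <- tempfile(fileext = ".pdb")
    writeLines(strsplit(pdb, "\n", fixed = TRUE)[[1]], path)
    on.exit(unlink(path))
  }
  parsed <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                     error = function(e) abort_mgvs(
                       paste("PDB parse failure:", conditionMessage(e)),
                       "mgvs_format_error"))
  at <- parsed$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  at <- at[at$resid != "HOH", , drop = FALSE]
  if (!nrow(at)) {
    abort_mgvs("no protein ATOM records in input", "mgvs_empty_structure_error")
  }
  if (anyNA(at$x) || anyNA(at$y) || anyNA(at$z)) {
    abort_mgvs("non-numeric coordinates in ATOM records", "mgvs_format_error")
  }
  elesy <- as.character(at$elesy)
  blank <- is.na(elesy) | !nzchar(trimws(elesy))
  if (any(blank)) {
    elesy[blank] <- infer_element(at$elety[blank])
  }
  atoms <- data.frame(
    chain = as.character(at$chain), resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resid = as.character(at$resid), elety = as.character(at$elety),
    elesy = elesy, x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE)
  rec <- structure(list(atoms = atoms, box_center = as.numeric(box_center),
                        box_edge = as.numeric(box_edge), id = id),
                   class = "mgvs_receptor")
  if (!any(rec$atoms$elesy == "H")) {
    rec <- add_backbone_amide_h(rec)
  }
  rec
}

# Atom-name -> element inference for protein ATOM records. Protein atom
# names start with the element letter once leading digits are stripped
# ("CA" is an alpha carbon here, not calcium — calcium only occurs in
# HETATM records, which are dropped).
infer_element <- function(names) {
  vapply(names, function(nm) {
    s <- gsub("[0-9']", "", trimws(nm))
    first <- toupper(substr(s, 1, 1))
    if (first %in% c("C", "N", "O", "S", "H", "P")) first else toupper(s)
  }, "", USE.NAMES = FALSE)
}

residue_key <- function(chain, resno, insert, resid) {
  paste0(chain, ":", resno, ifelse(nzchar(insert), paste0("^", insert), ""),
         ":", resid)
}

#' Residue keys of a receptor
#' @param rec a `mgvs_receptor`.
#' @return character vector (one per atom) of `chain:number[:icode]:name`.
#' @export
receptor_residue_keys <- function(rec) {
  with(rec$atoms, residue_key(chain, resno, insert, resid))
}

#' @export
print.mgvs_receptor <- function(x, ...) {
  cat(sprintf("<receptor %s: %d atoms, %d residues, box %.0f A at (%.1f, %.1f, %.1f)>\n",
              x$id, nrow(x$atoms), length(unique(receptor_residue_keys(x))),
              x$box_edge, x$box_center[1], x$box_center[2], x$box_center[3]))
  invisible(x)
}

# Idealized backbone amide hydrogen: H on the bisector of CA-N and C(prev)-N,
# 1.01 A from N. First residue of a chain and prolines get none.
add_backbone_amide_h <- function(rec) {
  at <- rec$atoms
  keys <- receptor_residue_keys(rec)
  res_order <- unique(keys)
  extra <- list()
  for (i in seq_along(res_order)) {
    sel <- which(keys == res_order[[i]])
    resid <- at$resid[sel[1]]
    if (resid == "PRO") next
    nidx <- sel[at$elety[sel] == "N"]
    caidx <- sel[at$elety[sel] == "CA"]
    if (!length(nidx) || !length(caidx)) next
    if (i == 1L) next
    prev <- which(keys == res_order[[i - 1L]])
    if (at$chain[prev[1]] != at$chain[sel[1]]) next
    cidx <- prev[at$elety[prev] == "C"]
    if (!length(cidx)) next
    N <- as.numeric(at[nidx[1], c("x", "y", "z")])
    CA <- as.numeric(at[caidx[1], c("x", "y", "z")])
    C <- as.numeric(at[cidx[1], c("x", "y", "z")])
    u <- unit3(N - CA) + unit3(N - C)
    if (sum(u^2) < 1e-8) next
    H <- N + 1.01 * unit3(u)
    extra[[length(extra) + 1L]] <- data.frame(
      chain = at$chain[nidx[1]], resno = at$resno[nidx[1]],
      insert = at$insert[nidx[1]], resid = resid, elety = "H",
      elesy = "H", x = H[1], y = H[2], z = H[3], stringsAsFactors = FALSE)
  }
  if (length(extra)) {
    rec$atoms <- rbind(at, do.call(rbind, extra))
  }
  rec
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(v * 0)
  v / n
}

# Is a point inside the receptor's docking box?
in_box <- function(rec, xyz) {
  all(abs(xyz - rec$box_center) <= rec$box_edge / 2)
}
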
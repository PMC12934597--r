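# Molecule parsing and representation.
#
# A `mgvs_mol` is a light heavy-atom graph view of a sanitized molecule:
# per-atom element / formal charge / aromatic flag, per-bond order with an
# aromatic flag, plus the canonical SMILES the structure round-trips to.
# Parsing, sanitization and canonicalization are delegated to OpenBabel
# through ChemmineR/ChemmineOB; this file only reshapes their output.

V2000_CHARGE_CODES <- c(`1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                        `5` = -1L, `6` = -2L, `7` = -3L)

#' Parse a molecule from SMILES or an SDF block
#'
#' Accepts either a single-line SMILES string or a complete SDF (V2000)
#' record. The structure is sanitized and aromaticity-perceived by OpenBabel;
#' the returned record stores the heavy-atom graph (explicit hydrogens in the
#' input are accepted and folded into implicit hydrogen counts) together with
#' the canonical SMILES.
#'
#' @param text SMILES string or SDF block.
#' @param id record identifier, used in error messages and downstream tables.
#' @param source free-form provenance tag (e.g. `"generated"`, `"library:toy"`).
#' @return A `mgvs_mol` object: list with `id`, `smiles` (canonical), `source`,
#'   `atoms` (data.frame: `element`, `charge`, `aromatic`), `bonds`
#'   (data.frame: `a1`, `a2`, `order`, `aromatic`).
#' @examples
#' \donttest{
#' bz <- parse_molecule("c1ccccc1", "bz")
#' n_heavy_atoms(bz)
#' }
#' @export
parse_molecule <- function(text, id, source = "input") {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    abort_mgvs(sprintf("empty molecule input for record '%s'", id),
               "mgvs_parse_error")
  }
  is_sdf <- grepl("V2000", text, fixed = TRUE) || grepl("\n", text, fixed = TRUE)
  if (is_sdf) {
    can <- suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", text))
  } else {
    can <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", text))
  }
  can <- sub("[\t ].*$", "", sub("\n.*$", "", can))
  if (!nzchar(can)) {
    abort_mgvs(sprintf("unparseable molecule for record '%s': %s", id,
                       substr(text, 1, 60)), "mgvs_parse_error")
  }
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(can, id))),
    error = function(e) abort_mgvs(
      sprintf("sanitization failed for record '%s': %s", id,
              conditionMessage(e)), "mgvs_parse_error")
  )
  mol_from_sdfset(sdfset, 1L, id = id, source = source, smiles = can)
}

# Build a mgvs_mol from one member of a ChemmineR SDFset.
mol_from_sdfset <- function(sdfset, i, id, source, smiles = NULL) {
  sdf <- sdfset[[i]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  charges <- rep(0L, nrow(ab))
  if ("C6" %in% colnames(ab)) {
    code <- as.character(as.integer(ab[, "C6"]))
    known <- code %in% names(V2000_CHARGE_CODES)
    charges[known] <- V2000_CHARGE_CODES[code[known]]
  }
  # "M  CHG" property lines override the old-style atom field when present
  # single-atom records cannot round-trip through SDFstr; they carry no
  # M CHG block either, so fall back to the atom-field charges alone
  txt <- tryCatch(methods::slot(methods::as(sdfset[i], "SDFstr"), "a")[[1]],
                  error = function(e) character(0))
  chg_lines <- grep("^M  CHG", txt, value = TRUE)
  if (length(chg_lines)) {
    for (ln in chg_lines) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[ ]+")[[1]])
      nrec <- f[1]
      for (k in seq_len(nrec)) charges[f[2 * k]] <- f[2 * k + 1]
    }
  }
  nb <- if (is.null(dim(bb)) || ncol(bb) < 3L) 0L else nrow(bb)
  bonds <- if (nb > 0L) {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  } else {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  }
  arom_atoms <- rep(FALSE, length(elements))
  ring_info <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf, type = "all", arom = TRUE)),
    error = function(e) NULL)
  if (!is.null(ring_info) && length(ring_info$RINGS)) {
    for (ri in seq_along(ring_info$RINGS)) {
      if (isTRUE(ring_info$AROMATIC[[ri]])) {
        idx <- match(ring_info$RINGS[[ri]], rownames(ab))
        arom_atoms[idx] <- TRUE
      }
    }
  }
  bonds$aromatic <- arom_atoms[bonds$a1] & arom_atoms[bonds$a2] &
    bond_in_ring(bonds, length(elements))
  # drop explicit hydrogens from the heavy-atom view
  keep <- elements != "H"
  if (!any(keep)) {
    abort_mgvs(sprintf("record '%s' has no heavy atoms", id), "mgvs_parse_error")
  }
  if (!all(keep)) {
    remap <- cumsum(keep)
    bkeep <- keep[bonds$a1] & keep[bonds$a2]
    bonds <- bonds[bkeep, , drop = FALSE]
    bonds$a1 <- remap[bonds$a1]
    bonds$a2 <- remap[bonds$a2]
    elements <- elements[keep]
    charges <- charges[keep]
    arom_atoms <- arom_atoms[keep]
  }
  atoms <- data.frame(element = elements, charge = as.integer(charges),
                      aromatic = arom_atoms, stringsAsFactors = FALSE)
  if (is.null(smiles)) {
    smiles <- canonical_smiles_of_sdf(sdfset[i])
  }
  structure(list(id = id, smiles = smiles, source = source,
                 atoms = atoms, bonds = bonds),
            class = "mgvs_mol")
}

# flag bonds that belong to at least one ring (via the cycle space of the
# heavy-atom graph); used only to restrict aromatic bond flags to rings
bond_in_ring <- function(bonds, n) {
  if (nrow(bonds) == 0L) return(logical(0))
  g <- igraph::make_graph(rbind(bonds$a1, bonds$a2), n = n, directed = FALSE)
  br <- igraph::bridges(g)
  res <- rep(TRUE, nrow(bonds))
  res[as.integer(br)] <- FALSE
  res
}

canonical_smiles_of_sdf <- function(sdfset1) {
  txt <- paste(unlist(methods::slot(methods::as(sdfset1, "SDFstr"), "a")),
               collapse = "\n")
  can <- suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", txt))
  sub("[\t ].*$", "", sub("\n.*$", "", can))
}

#' Canonical SMILES of a molecule record
#' @param mol a `mgvs_mol`.
#' @return Canonical SMILES string.
#' @export
canonical_smiles <- function(mol) {
  stopifnot(inherits(mol, "mgvs_mol"))
  mol$smiles
}

#' Number of heavy atoms
#' @param mol a `mgvs_mol`.
#' @export
n_heavy_atoms <- function(mol) nrow(mol$atoms)

#' @export
print.mgvs_mol <- function(x, ...) {
  cat(sprintf("<mgvs_mol %s> %s  (%d heavy atoms, %d bonds, source=%s)\n",
              x$id, x$smiles, nrow(x$atoms), nrow(x$bonds), x$source))
  invisible(x)
}

#' Read a SMILES file
#'
#' One record per line, `SMILES<TAB>id` (a bare SMILES gets a positional id).
#' Blank lines and `#` comments are skipped.
#'
#' @param path file path.
#' @param source provenance tag attached to every record.
#' @return list of `mgvs_mol`.
#' @export
read_smiles_file <- function(path, source = "file") {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "[\t ]+")[[1]]
    id <- if (length(f) >= 2) f[[2]] else sprintf("mol%04d", i)
    out[[i]] <- parse_molecule(f[[1]], id, source = source)
  }
  ids <- vapply(out, function(m) m$id, "")
  if (anyDuplicated(ids)) {
    abort_mgvs(sprintf("duplicate molecule ids in %s: %s", path,
                       paste(unique(ids[duplicated(ids)]), collapse = ", ")),
               "mgvs_input_error")
  }
  stats::setNames(out, ids)
}

#' Read a multi-record SDF file
#' @param path file path.
#' @param source provenance tag.
#' @return list of `mgvs_mol` named by molecule id (SDF title, or positional).
#' @export
read_sdf_file <- function(path, source = "file") {
  lines <- readLines(path, warn = FALSE)
  ends <- which(trimws(lines) == "$$$$")
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  out <- list()
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    if (!any(nzchar(trimws(block)))) next
    ttl <- trimws(block[[1]])
    id <- if (nzchar(ttl)) ttl else sprintf("mol%04d", k)
    out[[length(out) + 1L]] <- parse_molecule(paste(block, collapse = "\n"),
                                              id, source = source)
  }
  ids <- vapply(out, function(m) m$id, "")
  stats::setNames(out, make.unique(ids))
}

#' Write molecules to a SMILES file
#' @param mols list of `mgvs_mol`.
#' @param path output path.
#' @export
write_smiles_file <- function(mols, path) {
  lines <- vapply(mols, function(m) paste0(m$smiles, "\t", m$id), "")
  writeLines(lines, path)
  invisible(path)
}
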
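# Path-based (Daylight-style) and circular (ECFP-style) fingerprints with
# Tanimoto distances. Bit generation is delegated to OpenBabel (FP2 linear
# paths up to 7 bonds; ECFP circular environments); folding to the requested
# width is done here by OR-combining aligned blocks, which preserves
# determinism and platform stability.

new_fingerprint <- function(kind, bits) {
  structure(list(kind = kind, bits = as.logical(bits)), class = "mgvs_fp")
}

#' @export
print.mgvs_fp <- function(x, ...) {
  cat(sprintf("<%s fingerprint: %d bits, %d set>\n", x$kind, length(x$bits),
              sum(x$bits)))
  invisible(x)
}

ob_fingerprint <- function(mol, name) {
  res <- ChemmineOB::forEachMol("SMILES", mol$smiles, function(m) {
    ChemmineOB::fingerprint_OB(list(m), name)
  })
  bits <- as.numeric(res[[1]]) > 0
  bits
}

fold_bits <- function(bits, nbits) {
  n <- length(bits)
  if (nbits == n) return(bits)
  if (nbits > n || n %% nbits != 0L) {
    abort_mgvs(sprintf("cannot fold a %d-bit fingerprint to %d bits", n, nbits),
               "mgvs_argument_error")
  }
  folded <- rep(FALSE, nbits)
  for (b in seq_len(n %/% nbits)) {
    folded <- folded | bits[seq.int((b - 1L) * nbits + 1L, b * nbits)]
  }
  folded
}

#' Path-based (Daylight-style) fingerprint
#'
#' Hashed enumeration of linear atom-bond paths up to 7 bonds (the OpenBabel
#' FP2 scheme, natively 1024 bits). Longer widths are not available from the
#' generator; narrower widths are obtained by folding.
#'
#' @param mol a `mgvs_mol`.
#' @param nbits fingerprint width; must divide 1024. Default 1024.
#' @return A `mgvs_fp` of kind `"path"`.
#' @export
path_fingerprint <- function(mol, nbits = 1024) {
  stopifnot(inherits(mol, "mgvs_mol"))
  new_fingerprint("path", fold_bits(ob_fingerprint(mol, "FP2"), nbits))
}

#' Circular (ECFP-style) fingerprint
#'
#' Extended-connectivity environments of the given radius; radius 2 is ECFP4.
#' Natively 4096 bits from the generator, folded to `nbits`.
#'
#' @param mol a `mgvs_mol`.
#' @param radius circular environment radius in bonds (default 2 = ECFP4).
#' @param nbits fingerprint width; must divide 4096. Default 2048.
#' @return A `mgvs_fp` of kind `"circular-r<radius>"`.
#' @export
circular_fingerprint <- function(mol, radius = 2, nbits = 2048) {
  stopifnot(inherits(mol, "mgvs_mol"), radius >= 0)
  name <- paste0("ECFP", 2L * as.integer(radius))
  new_fingerprint(paste0("circular-r", as.integer(radius)),
                  fold_bits(ob_fingerprint(mol, name), nbits))
}

#' Tanimoto distance between two fingerprints
#'
#' `1 - |a AND b| / |a OR b|`: 0 for identical non-empty fingerprints, 1 for
#' disjoint ones. Low distance means similar.
#'
#' @param a,b `mgvs_fp` objects of the same kind and width.
#' @return Numeric in `[0, 1]`.
#' @export
tanimoto_distance <- function(a, b) {
  if (!inherits(a, "mgvs_fp") || !inherits(b, "mgvs_fp")) {
    abort_mgvs("tanimoto_distance expects two fingerprints", "mgvs_argument_error")
  }
  if (a$kind != b$kind || length(a$bits) != length(b$bits)) {
    abort_mgvs(sprintf("fingerprint kind/length mismatch: %s/%d vs %s/%d",
                       a$kind, length(a$bits), b$kind, length(b$bits)),
               "mgvs_argument_error")
  }
  un <- sum(a$bits | b$bits)
  if (un == 0L) return(0)
  1 - sum(a$bits & b$bits) / un
}
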
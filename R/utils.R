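#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_mgvs <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "mgvs_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# FNV-1a 32-bit string hash, kept in integer arithmetic that stays exact in
# doubles (< 2^53). Used wherever a platform-stable deterministic hash is
# needed (mock engine, fingerprint folding of tagged features).
# 32-bit modular multiply carried out in pieces so every intermediate stays
# exactly representable in a double.
mulmod32 <- function(a, b) {
  lo <- a %% 65536
  hi <- a %/% 65536
  (lo * b + ((hi * b) %% 65536) * 65536) %% 4294967296
}

fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- mulmod32(h, 16777619)
  }
  h
}

# Deterministic uniform in [0,1) from a string key (multiplicative remix of
# the FNV hash so nearby keys decorrelate).
hash_unit <- function(s) {
  h <- fnv1a32(s)
  h <- mulmod32(h, 2654435761)
  h <- (h + mulmod32(h %/% 65536, 40503)) %% 4294967296
  h / 4294967296
}

# Fixed-format number rendering for TSV/JSON artifacts so repeated runs are
# byte-identical across platforms.
fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}

write_tsv_artifact <- function(df, path) {
  stopifnot(is.data.frame(df))
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.numeric(df2[[j]]) && !is.integer(df2[[j]])) df2[[j]] <- fmt_num(df2[[j]])
  }
  utils::write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv_artifact <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "")
}

# Sub-seed derivation: keeps derived seeds positive and below 2^31.
derive_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 48271 + fnv1a32(tag)) %% 2147483629) + 1L
}

has_obabel <- function() nzchar(Sys.which("obabel"))

run_obabel <- function(args, stdin_text = NULL) {
  exe <- Sys.which("obabel")
  if (!nzchar(exe)) {
    abort_mgvs("obabel executable not found on PATH", "mgvs_config_error")
  }
  out <- tryCatch(
    system2(exe, args, stdout = TRUE, stderr = TRUE, input = stdin_text),
    error = function(e) abort_mgvs(paste("obabel invocation failed:", conditionMessage(e)),
                                   "mgvs_engine_error")
  )
  out
}
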
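# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a per-stage seed from a master seed; kept below .Machine$integer.max
# so set.seed() always receives a valid 32-bit integer.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) %% 2147483647) * 31 + stage) %% 2147483629L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stopf("%s must lie in [0, 1]", name)
  }
  invisible(x)
}

# Open a text connection, transparently handling gzip (gzfile also reads
# uncompressed files).
open_text <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  gzfile(path, open = "rt")
}
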
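# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.  seed = NULL leaves the RNG alone.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # force RNG initialisation so we have state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' @keywords internal
#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Check a scalar is a single finite number.
#' @keywords internal
#' @noRd
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# FNV-1a hash of a character string, returned as 8 hex digits.  Used to stamp
# output files with a config fingerprint; not cryptographic.
#' @keywords internal
#' @noRd
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 0x811c9dc5
  for (b in bytes) {
    # xor touches only the low byte (b < 256); keep h as a double
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime, split so doubles stay exact
    h0 <- h %% 65536
    h1 <- (h - h0) / 65536
    h <- (h0 * 16777619 + (h1 * 16777619 %% 65536) * 65536) %% 4294967296
  }
  # format as 8 hex digits (h is a double; render via two 16-bit halves)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
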
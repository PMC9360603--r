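# Internal helpers: scoped RNG, integer seed derivation, FNV-1a hashing.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from (seed, stream indices), kept within 32-bit range.
# Splitmix-style integer mixing so nearby parent seeds give unrelated streams.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- (as.double(seed) %% 2147483647) + 1
  for (i in idx) {
    h <- (h * 2654435761 + as.double(i) * 40503 + 12345) %% 2147483647
  }
  as.integer(h %% 2147483629 + 1)
}

xor32 <- function(a, b) {
  bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536)) * 65536 +
    bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
}

mul32 <- function(a, b) {
  lo <- a %% 65536
  hi <- a %/% 65536
  (((hi * b) %% 65536) * 65536 + lo * b) %% 4294967296
}

# FNV-1a 32-bit hash of a character string, returned as "%08x".
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    h <- mul32(h, 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("cossvep_domain_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("cossvep_config_error", "error")))
}

stop_alignment <- function(...) {
  stop(errorCondition(paste0(...), class = c("cossvep_alignment_error", "error")))
}

stop_integrity <- function(...) {
  stop(errorCondition(paste0(...), class = c("cossvep_integrity_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
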
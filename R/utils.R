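# Internal helpers.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Derive a stream-specific 31-bit seed from a base seed and stream labels.
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(c(...)))
  h <- 0
  for (p in parts) h <- (h * 69069 + p) %% 2147483647
  as.integer(h)
}

log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

# All permutations of 1..n (n small; used for mixture label alignment).
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Polynomial rolling hash of a character scalar, as 8 hex digits (config
# fingerprinting only; not cryptographic).
fnv1a_hash <- function(x) {
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
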
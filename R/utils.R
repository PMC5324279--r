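# Internal helpers: seeded RNG isolation and stable string hashing.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. All stochastic operations in the package go through this so that
# a single user-facing seed fully determines every output.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit hash of one or more strings/integers, used to derive
# per-allele / per-gene sub-seeds from the run seed. Polynomial rolling hash
# in double precision (exact below 2^53), reduced mod 2^31 - 1.
hash_seed <- function(...) {
  parts <- paste(c(...), collapse = "\x1f")
  codes <- utf8ToInt(parts)
  h <- 5381
  m <- 2147483647
  for (k in codes) {
    h <- (h * 33 + k) %% m
  }
  as.integer(h)
}

# Random amino-acid strings of the given lengths (uses the current RNG
# stream; callers wrap in with_seed()).
random_aa <- function(lengths) {
  vapply(
    lengths,
    function(L) paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = ""),
    character(1)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
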
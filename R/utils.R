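# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators behave as pure functions of their seed.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive a stream seed from a master seed. Kept below 2^31
# and exactly representable in doubles.
derive_seed <- function(seed, offset) {
  s <- (abs(as.double(seed)) %% 1e6) + 1
  as.integer((s * 7919 + (abs(as.double(offset)) %% 1e6) * 104729) %% 2147483629)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# Half-up rounding to integer (used when reporting ages in KY).
round_half_up <- function(x) floor(x + 0.5)
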
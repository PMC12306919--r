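# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library functions never clobber user RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Sub-seed derivation: deterministic, stays well inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + (as.integer(offset) %% 1000L)
}

# Nearest-integer percentage, rounding halves up (plain "round to nearest").
percent_int <- function(count, denominator) {
  stopifnot(denominator > 0, count >= 0)
  as.integer(floor(100 * count / denominator + 0.5))
}

# Fisher z with clipping so duplicated series stay finite.
fisher_z <- function(r, clip = 1 - 1e-7) atanh(pmin(pmax(r, -clip), clip))

inv_fisher_z <- function(z) tanh(z)

upper_tri_values <- function(m) m[upper.tri(m)]

# Replace the undefined diagonal with 0 (for interop with dist-based tools).
strip_na_diag <- function(m) {
  m <- unclass(m)
  diag(m) <- 0
  m
}

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
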
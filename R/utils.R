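# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards, so generators are pure functions of (args, seed).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Population standard deviation (denominator n): matches the two-point
# standardization contract and the plug-in covariances used downstream.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# z-score with population sd; returns NULL for (numerically) constant input
# so callers can flag rather than divide by ~0.
zscore_vec <- function(x, tol = 1e-12) {
  s <- sd_pop(x)
  if (!is.finite(s) || s < tol) return(NULL)
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}
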
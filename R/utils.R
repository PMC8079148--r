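# internal helpers

# Evaluate `expr` with the RNG seeded to `seed`, restoring any pre-existing
# global RNG state afterwards.  All stochastic operations in the package go
# through this so nothing leaks into (or depends on) .Random.seed.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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

stop_if_not_scalar_pos <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (if (allow_zero) x < 0 else x <= 0)) {
    stop(sprintf("`%s` must be a single %s number", name,
                 if (allow_zero) "nonnegative" else "positive"), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
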
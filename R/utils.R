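# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All exported stochastic functions route their randomness
# through this so identical (input, seed) pairs give identical output.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict && x <= min) {
    stop(sprintf("`%s` must be > %g", name, min), call. = FALSE)
  }
  if (!strict && x < min) {
    stop(sprintf("`%s` must be >= %g", name, min), call. = FALSE)
  }
  invisible(x)
}

# Round half away from zero, the convention used when rendering the
# cohort percentages as integers (e.g. 89.58 -> 90).
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
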
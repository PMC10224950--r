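# Internal helpers shared across the package.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package funnel through this so that any
# stage is independently reproducible from its own seed argument.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single number")
  }
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

# Derive a deterministic sub-seed for a named substream. Keeps derived seeds
# inside the 32-bit integer range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a

edge_key <- function(regulator, target) paste(regulator, target, sep = "\r")

stopifnot_scalar_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || any(!is.finite(x))) stop(name, " must be numeric and finite")
  if (open) {
    if (any(x <= 0) || any(x >= 1)) stop(name, " must lie strictly in (0,1)")
  } else {
    if (any(x < 0) || any(x > 1)) stop(name, " must lie in [0,1]")
  }
  invisible(x)
}
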
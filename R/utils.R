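# Internal helpers shared across modules.

# Evaluate expr under a given seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Componentwise clip into [lower, upper].
clipToBounds <- function(x, lower, upper) {
  pmin(pmax(x, lower), upper)
}

# Guard an objective: non-finite values become +Inf with a warning.
guardObjective <- function(objective) {
  function(x) {
    v <- objective(x)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      warning("objective returned a non-finite value; assigned +Inf",
              call. = FALSE)
      return(Inf)
    }
    as.numeric(v)
  }
}

# Rec. 709 luminance of an H x W x C pixel array (C = 1 passes through).
luminance <- function(px) {
  if (dim(px)[3] == 1L) return(px[, , 1L])
  0.2126 * px[, , 1L] + 0.7152 * px[, , 2L] + 0.0722 * px[, , 3L]
}
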
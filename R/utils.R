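# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library functions never clobber user RNG.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Deterministic sub-stream seeds: one global seed, fixed per-stage offsets.
subSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483629)
}

# Squared Euclidean cross-distances between rows of a and rows of b.
crossDist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

assertScalar <- function(x, name, lower = -Inf, upper = Inf,
                         openLower = FALSE, openUpper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  okL <- if (openLower) x > lower else x >= lower
  okU <- if (openUpper) x < upper else x <= upper
  if (!okL || !okU)
    stop(sprintf("'%s' = %g is out of range %s%g, %g%s", name, x,
                 if (openLower) "(" else "[", lower, upper,
                 if (openUpper) ")" else "]"))
  invisible(x)
}
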
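## Internal helpers.

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG state afterwards. All package randomness
## flows through this, so identical seeds give identical output
## regardless of the caller's RNG history.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("%s must be a single number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  invisible(x)
}

## 0-based half-open interval clamping shared by flank addition.
clampInterval <- function(start, end, chromLength) {
  cbind(pmax(0L, as.integer(start)),
        pmin(as.integer(chromLength), as.integer(end)))
}
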
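# Lattice medians: all component/path times live on the 1-ms bin lattice, so
# medians must return a lattice value. For even counts the lower median is used
# throughout the package.
.lowerMedian <- function(x) {
  stopifnot(length(x) > 0L)
  sort(x)[ceiling(length(x) / 2)]
}

# Two merged lattice times are replaced by the floor of their mean (the "median
# 1 ms bin between" them), keeping merged times on the lattice.
.floorMeanPair <- function(a, b) floor((a + b) / 2)

# Restore the caller's RNG state after seeded simulation.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

.assertScalarNumber <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}
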
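# Internal helpers: argument checking, seeded evaluation, unit conversion.

.assertScalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0 (got %g)", name, x), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0 (got %g)", name, x), call. = FALSE)
  invisible(x)
}

.assertCount <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.  Every generator in the package funnels through this, which is
# what makes each one a pure function of (parameters, seed).
.withSeed <- function(seed, expr) {
  seed <- .assertCount(seed, "seed", min = 0L)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic child seeds derived from one root seed (kept below 2^31).
.spawnSeeds <- function(seed, n) {
  .withSeed(seed, sample.int(2147483646L, n))
}

#' Convert degrees Celsius to kelvin
#'
#' Temperatures are kelvin everywhere inside the package; Celsius is accepted
#' only at configuration and file boundaries and converted on read.
#'
#' @param x numeric vector of temperatures in degrees Celsius.
#' @return numeric vector in kelvin.
#' @examples
#' celsiusToKelvin(c(12, 20, 38))
#' @export
celsiusToKelvin <- function(x) x + 273.15

# Simple local-maximum picker: indices i with x[i] > x[i-1], x[i] >= x[i+1],
# x[i] >= threshold, successive picks at least minGap samples apart.
.findPeaks <- function(x, threshold = -Inf, minGap = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= threshold]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(-x[cand])]
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) >= minGap)) keep <- c(keep, i)
  }
  sort(keep)
}
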
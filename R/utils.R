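#' Break ties by rank-preserving jitter
#'
#' Nonparametric density machinery assumes distinct values. Tied values are
#' separated by adding deterministic, rank-preserving noise of magnitude
#' `1e-9 * data range` so downstream results are reproducible.
#'
#' @param x numeric vector.
#' @param seed integer seed for the jitter stream.
#' @return numeric vector, same order as `x`, ties broken.
#' @keywords internal
#' @noRd
jitter_ties <- function(x, seed = 1L) {
  if (!anyDuplicated(x)) return(x)
  rng <- diff(range(x))
  if (rng == 0) rng <- max(abs(x[1]), 1)
  eps <- 1e-9 * rng
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  # rank-preserving: noise much smaller than the smallest nonzero gap
  x + rank(x, ties.method = "first") * eps / length(x) +
    runif(length(x), 0, eps / (10 * length(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic child seed derivation (kept below 2^31)
#' @noRd
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 10007) %% 2147483587)
}
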
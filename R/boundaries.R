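#' Default marker boundary matrix
#'
#' Per-marker lower and upper expression bounds used to shield the density
#' machinery from debris/doublet pile-ups at the extremes of the scale.
#' For each marker the 1st and 99th percentiles of expression are computed
#' per sample; the lower bound is the 5th percentile of the per-sample 1st
#' percentiles and the upper bound the 95th percentile of the per-sample
#' 99th percentiles. Events outside the bounds are never dropped: they are
#' flagged default-low / default-high, excluded from dip testing and density
#' estimation, and assigned to the extreme child populations when gating.
#'
#' @param samples list of [expression_matrix] objects sharing a marker panel.
#' @return numeric matrix with rows `low`, `high` and one column per marker.
#' @export
default_boundary_matrix <- function(samples) {
  stopifnot(length(samples) >= 1)
  mk <- samples[[1]]$markers
  p01 <- vapply(samples, function(s)
    apply(s$values, 2, quantile, probs = 0.01, names = FALSE), numeric(length(mk)))
  p99 <- vapply(samples, function(s)
    apply(s$values, 2, quantile, probs = 0.99, names = FALSE), numeric(length(mk)))
  if (length(mk) == 1) { p01 <- matrix(p01, 1); p99 <- matrix(p99, 1) }
  low  <- apply(matrix(p01, nrow = length(mk)), 1, quantile, probs = 0.05, names = FALSE)
  high <- apply(matrix(p99, nrow = length(mk)), 1, quantile, probs = 0.95, names = FALSE)
  if (any(low >= high)) {
    bad <- mk[low >= high]
    stop("marker(s) constant across samples: ", paste(bad, collapse = ", "),
         "; exclude them from the active marker list")
  }
  b <- rbind(low = low, high = high)
  colnames(b) <- mk
  b
}

#' Flag events relative to marker bounds
#' @param x numeric vector of one marker's expression.
#' @param bounds length-2 numeric `(low, high)`.
#' @return integer vector: 0 inside (strictly between), -1 at/below low,
#'   +1 at/above high.
#' @export
boundary_flags <- function(x, bounds) {
  f <- integer(length(x))
  f[x <= bounds[1]] <- -1L
  f[x >= bounds[2]] <- 1L
  f
}

#' Effective sample size of a marker
#'
#' The number of events strictly between the marker's lower and upper bounds;
#' only these events take part in dip testing and density estimation.
#'
#' @inheritParams boundary_flags
#' @return integer count.
#' @export
effective_sample_size <- function(x, bounds) {
  sum(x > bounds[1] & x < bounds[2])
}
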
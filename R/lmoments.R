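#' Trimmed sample L-moment ratios
#'
#' Sample TL-moments with symmetric trim 1 (each conceptual subsample drops
#' its smallest and largest element), following the direct order-statistic
#' weighting. Returns the trimmed L-skewness and L-kurtosis ratios
#' `tau3 = l3/l2` and `tau4 = l4/l2`, which are robust shape summaries of a
#' leaf margin: `tau3` is 0 for symmetric samples and `tau4` measures
#' peakedness relative to tail weight.
#'
#' @param x numeric vector with at least 6 values.
#' @return named numeric vector `c(tau3, tau4)`.
#' @export
trimmed_lmoment_ratios <- function(x) {
  n <- length(x)
  if (n < 6) return(c(tau3 = NA_real_, tau4 = NA_real_))
  x <- sort(x)
  i <- seq_len(n)
  c1 <- i - 1; c2 <- n - i
  l1 <- sum(choose(c1, 1) * choose(c2, 1) * x) / choose(n, 3)
  l2 <- sum((choose(c1, 2) * choose(c2, 1) - choose(c1, 1) * choose(c2, 2)) * x) /
    (2 * choose(n, 4))
  l3 <- sum((choose(c1, 3) * choose(c2, 1) - 2 * choose(c1, 2) * choose(c2, 2) +
               choose(c1, 1) * choose(c2, 3)) * x) / (3 * choose(n, 5))
  l4 <- sum((choose(c1, 4) * choose(c2, 1) - 3 * choose(c1, 3) * choose(c2, 2) +
               3 * choose(c1, 2) * choose(c2, 3) - choose(c1, 1) * choose(c2, 4)) * x) /
    (4 * choose(n, 6))
  if (l2 <= 0) return(c(tau3 = NA_real_, tau4 = NA_real_))
  c(tau3 = l3 / l2, tau4 = l4 / l2)
}
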
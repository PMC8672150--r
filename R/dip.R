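#' Hartigan dip test of unimodality
#'
#' Computes the dip statistic — the smallest sup-norm distance between the
#' empirical distribution function and any unimodal distribution function —
#' and calibrates a p-value against the uniform null. The p-value comes from
#' a precomputed Monte-Carlo quantile table (interpolated in `sqrt(n) * dip`
#' across sample sizes); for sample sizes outside the table a seeded
#' Monte-Carlo null of `mc_reps` replicates is simulated on the fly.
#'
#' @param x numeric vector (at least 4 values). Ties are broken by
#'   deterministic rank-preserving jitter.
#' @param mc_reps Monte-Carlo replicates for off-table sample sizes.
#' @return list of class `dip_result`: `statistic`, `p_value`, `n`.
#' @examples
#' d <- dip_test(c(rnorm(200), rnorm(200, 8)))
#' d$p_value < 0.01
#' @export
dip_test <- function(x, mc_reps = 10000L) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) stop("insufficient events for the dip test (n < 4)")
  x <- jitter_ties(x)
  stat <- .dip_stat_cpp(sort(x))
  structure(list(statistic = stat, p_value = dip_pvalue(stat, n, mc_reps), n = n),
            class = "dip_result")
}

#' @export
print.dip_result <- function(x, ...) {
  cat(sprintf("dip = %.5g, n = %d, p = %.4g\n", x$statistic, x$n, x$p_value))
  invisible(x)
}

.dip_env <- new.env(parent = emptyenv())

# consolidated per-node scan used by the forest code: gathers each marker's
# in-bounds events, computes dip + table p-value and (for rejected markers)
# taut-string gates in one compiled call
node_scan <- function(vals, idx, markers, bounds, dip_threshold, ts_scale,
                      max_gates, lazy = FALSE, min_scan = 25L) {
  tab <- dip_table()
  cols <- match(markers, colnames(vals))
  sc <- .node_scan_cpp(vals, as.integer(idx), as.integer(cols),
                       bounds[1, markers], bounds[2, markers],
                       dip_threshold, ts_scale, as.integer(max_gates),
                       as.integer(min_scan),
                       tab$n, tab$probs, tab$q, lazy)
  names(sc$n_eff) <- names(sc$p) <- names(sc$gates) <- names(sc$scanned) <- markers
  sc
}

dip_table <- function() {
  if (is.null(.dip_env$tab)) {
    path <- system.file("extdata", "dip_null_quantiles.csv", package = "phenoforest")
    tab <- utils::read.csv(path, check.names = FALSE)
    .dip_env$tab <- list(
      n = tab$n,
      probs = as.numeric(colnames(tab)[-1]),
      q = as.matrix(tab[, -1, drop = FALSE])
    )
  }
  .dip_env$tab
}

#' Dip p-value from the uniform-null calibration
#' @param stat dip statistic.
#' @param n sample size it was computed from.
#' @param mc_reps Monte-Carlo replicates used when `n` is outside the table.
#' @return p-value in (0, 1); values are clamped to the table's probability
#'   grid range.
#' @export
dip_pvalue <- function(stat, n, mc_reps = 10000L) {
  tab <- dip_table()
  if (n >= min(tab$n) && n <= max(tab$n)) {
    i <- findInterval(n, tab$n)
    if (tab$n[i] == n) {
      q <- tab$q[i, ]
    } else {
      # interpolate sqrt(n)-scaled quantiles linearly in log(n)
      w <- (log(n) - log(tab$n[i])) / (log(tab$n[i + 1]) - log(tab$n[i]))
      qs <- (1 - w) * sqrt(tab$n[i]) * tab$q[i, ] + w * sqrt(tab$n[i + 1]) * tab$q[i + 1, ]
      q <- qs / sqrt(n)
    }
    cdf <- approx(q, tab$probs, xout = stat, rule = 2, ties = "ordered")$y
    return(1 - cdf)
  }
  key <- paste0("mc", n)
  null <- .dip_env[[key]]
  if (is.null(null)) {
    null <- .dip_null_cpp(as.integer(n), as.integer(mc_reps), 77003L)
    .dip_env[[key]] <- null
  }
  (1 + sum(null >= stat)) / (length(null) + 1)
}
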
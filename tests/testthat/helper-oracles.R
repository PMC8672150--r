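# Independent oracles used to validate the package's nonparametric
# primitives. These deliberately take different algorithmic routes from the
# implementations they check.

# ---- exact dip oracle: binary search on the sup distance + feasibility ----
# feasibility of distance e: exists a junction knot k such that a convex
# function fits the tube on 1..k, a concave one on k..n, and their achievable
# junction-value intervals intersect (pairwise line bounds).
oracle_gcm_vals <- function(xx, yy) {
  n <- length(xx); hull <- 1L
  if (n >= 2) for (i in 2:n) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      if ((yy[b] - yy[a]) * (xx[i] - xx[a]) >= (yy[i] - yy[a]) * (xx[b] - xx[a]))
        hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  v <- numeric(n)
  for (j in seq_len(n)) {
    k <- findInterval(j, hull)
    if (j == hull[k]) v[j] <- yy[j]
    else {
      a <- hull[k]; b <- hull[k + 1]
      v[j] <- yy[a] + (yy[b] - yy[a]) * (xx[j] - xx[a]) / (xx[b] - xx[a])
    }
  }
  v
}

oracle_dip_feasible <- function(x, e) {
  n <- length(x)
  Lv <- (1:n) / n - e
  Uv <- (0:(n - 1)) / n + e
  if (any(Lv > Uv + 1e-15)) return(FALSE)
  pref_ok <- logical(n); amin <- numeric(n)
  for (k in 1:n) {
    g <- oracle_gcm_vals(x[1:k], Uv[1:k])
    pref_ok[k] <- all(g >= Lv[1:k] - 1e-13)
    am <- Lv[k]
    if (k >= 2) for (j in 2:k) for (i in 1:(j - 1)) {
      sl <- (Lv[j] - Uv[i]) / (x[j] - x[i])
      am <- max(am, Uv[i] + sl * (x[k] - x[i]))
    }
    amin[k] <- am
  }
  suf_ok <- logical(n); bmax <- numeric(n)
  for (k in n:1) {
    l <- -oracle_gcm_vals(x[k:n], -Lv[k:n])
    suf_ok[k] <- all(l <= Uv[k:n] + 1e-13)
    bm <- Uv[k]
    if (k <= n - 1) for (i in k:(n - 1)) for (j in (i + 1):n) {
      sl <- (Lv[j] - Uv[i]) / (x[j] - x[i])
      bm <- min(bm, Uv[i] + sl * (x[k] - x[i]))
    }
    bmax[k] <- bm
  }
  any(pref_ok & suf_ok & (pmax(amin, Lv) <= pmin(bmax, Uv) + 1e-13))
}

oracle_dip <- function(x, tol = 1e-9) {
  x <- sort(x); n <- length(x)
  lo <- 1 / (2 * n) - 1e-12; hi <- 0.25 + 1e-9
  if (oracle_dip_feasible(x, lo + 1e-12)) return(1 / (2 * n))
  for (it in 1:55) {
    mid <- (lo + hi) / 2
    if (oracle_dip_feasible(x, mid)) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  hi
}

# ---- taut string oracle: box-constrained energy minimization -------------
oracle_taut_string <- function(x, r) {
  x <- sort(x); n <- length(x)
  f <- c(0, ((2:(n - 1)) - 0.5) / n, 1)
  lb <- pmax(0, f - r); ub <- pmin(1, f + r)
  lb[1] <- ub[1] <- 0; lb[n] <- ub[n] <- 1
  dx <- diff(x)
  fn <- function(v) sum(diff(v)^2 / dx)
  gr <- function(v) { s <- 2 * diff(v) / dx; c(-s[1], s[-length(s)] - s[-1], s[length(s)]) }
  stats::optim((lb + ub) / 2, fn, gr, method = "L-BFGS-B",
               lower = lb, upper = ub,
               control = list(maxit = 20000, factr = 1e1))$par
}

# ---- trimmed L-moment oracle: expectation over all (r+2)-subsets ---------
oracle_tlmoments <- function(x) {
  x <- sort(x); n <- length(x)
  eo <- function(r, j) {   # E[X_{(j)} : subsample of size r]
    mean(combn(n, r, function(ii) sort(x[ii])[j]))
  }
  l1 <- eo(3, 2)
  l2 <- (eo(4, 3) - eo(4, 2)) / 2
  l3 <- (eo(5, 4) - 2 * eo(5, 3) + eo(5, 2)) / 3
  l4 <- (eo(6, 5) - 3 * eo(6, 4) + 3 * eo(6, 3) - eo(6, 2)) / 4
  c(tau3 = l3 / l2, tau4 = l4 / l2)
}

# ---- small synthetic FCS writer (binary fixture built at test time) ------
write_synthetic_fcs <- function(path, values, pns = colnames(values),
                                pnn = sprintf("FL%d-A", seq_len(ncol(values)))) {
  npar <- ncol(values); ntot <- nrow(values)
  kv <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$PAR", npar, "$TOT", ntot, "$NEXTDATA", "0")
  for (i in seq_len(npar)) {
    kv <- c(kv, sprintf("$P%dN", i), pnn[i], sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0", sprintf("$P%dR", i), "262144")
    if (!is.null(pns) && nzchar(pns[i]))
      kv <- c(kv, sprintf("$P%dS", i), pns[i])
  }
  delim <- "/"
  text <- paste0(delim, paste(kv, collapse = delim), delim)
  text_beg <- 58
  text_end <- text_beg + nchar(text) - 1
  data_beg <- text_end + 1
  data_end <- data_beg + 4 * npar * ntot - 1
  hdr <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                 text_beg, text_end, data_beg, data_end, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.vector(t(values)), con, size = 4, endian = "little")
  invisible(path)
}

# small bimodal helper used across tests
bimodal_sample <- function(n, gap = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  c(rnorm(ceiling(n / 2)), rnorm(floor(n / 2), gap))
}
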
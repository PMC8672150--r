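#' Reference mixture weight vector (127 components)
#'
#' The benchmark's reference probability vector: 1 component at 0.1425, 2 at
#' 0.07125, 4 at 0.035625, 8 at 0.0178125, 16 at 0.00890625, 32 at
#' 0.004453125 and 64 at 0.002226562, in decreasing order. The first
#' `n_clusters` entries, renormalized by spreading the residual mass
#' uniformly, define a simulated experiment's mixture weights.
#'
#' @return numeric vector of length 127.
#' @export
reference_weights <- function() {
  rep(c(0.1425, 0.07125, 0.035625, 0.0178125, 0.00890625, 0.004453125,
        0.002226562),
      times = c(1L, 2L, 4L, 8L, 16L, 32L, 64L))
}

# fixed 125-component weight vectors of the responder benchmark; the
# predictive component sits at position 120 (weight doubled in responders)
responder_weights <- function(responder = FALSE) {
  v2 <- c(0.16155, rep(0.0712, 2), rep(0.0356, 4), rep(0.0178, 8),
          rep(0.0089, 16), rep(0.0045, 32), rep(0.0022, 47),
          0.00209, 0.00198, 0.00187, 0.00176, 0.00165, 0.00154, 0.00143,
          0.00132, 0.00121, rep(0.0011, 6))
  v3 <- c(0.16120344, rep(0.07105221, 2), rep(0.03553053, 4),
          rep(0.01776969, 8), rep(0.00888927, 16), rep(0.00449895, 32),
          rep(0.00220401, 47),
          0.00209425, 0.0019845, 0.00187474, 0.00176498, 0.00165522,
          0.00154546, 0.00143571, 0.00132595, 0.00121619, 0.0022,
          rep(0.00110643, 5))
  if (responder) v3 else v2
}

#' Index of the predictive component in the responder benchmark
#' @export
predictive_component <- function() 120L

random_covariance <- function(dim) {
  W <- matrix(rnorm(dim * dim), dim)
  R <- stats::cov2cor(W %*% t(W))
  s <- sqrt(runif(dim, 1, 2))
  R * tcrossprod(s)
}

draw_mixture_sample <- function(weights, mu, n_obs, dim, mean_sd = 0.5) {
  sizes <- as.vector(rmultinom(1, n_obs, weights))
  k <- length(weights)
  X <- matrix(0, n_obs, dim)
  labels <- integer(n_obs)
  pos <- 0L
  for (c_ in seq_len(k)) {
    nc <- sizes[c_]
    if (nc == 0) next
    mu_c <- mu[c_, ] + round(rnorm(dim, 0, mean_sd))
    Sig <- random_covariance(dim)
    Z <- matrix(rnorm(nc * dim), nc) %*% chol(Sig)
    X[pos + seq_len(nc), ] <- sweep(Z, 2, mu_c, "+")
    labels[pos + seq_len(nc)] <- c_
    pos <- pos + nc
  }
  list(values = X, labels = labels)
}

#' Simulate a multivariate Gaussian mixture experiment
#'
#' Generates `n_samples` samples of `n_obs` cells from a `dim`-dimensional
#' Gaussian mixture. Mixture weights are the first `n_clusters` reference
#' weights with uniform residual redistribution; component mean vectors have
#' entries drawn from {0 (not expressed), 8 (expressed)} and are distinct
#' across components; covariances have variances uniform between 1 and 2 with
#' random correlation, redrawn per sample and component; each component's
#' mean is perturbed per sample by integer-rounded N(0, 1/2^2) shifts.
#'
#' @param n_clusters number of mixture components (1-127).
#' @param n_samples samples per experiment.
#' @param n_obs cells per sample.
#' @param dim number of markers.
#' @param seed integer seed.
#' @param weights optional explicit weight vector (overrides the reference
#'   subsetting; used by the responder benchmark).
#' @param mu optional fixed component-mean matrix (components x dim).
#' @return object of class `simulated_experiment`: list of
#'   [expression_matrix], per-sample true labels, the generating parameters.
#' @export
simulate_gaussian_experiment <- function(n_clusters, n_samples = 10L,
                                         n_obs = 25000L, dim = 10L, seed = 1L,
                                         weights = NULL, mu = NULL) {
  if (is.null(weights)) {
    if (n_clusters < 1 || n_clusters > 127) stop("n_clusters must be in 1..127")
    w <- reference_weights()[seq_len(n_clusters)]
    w <- w + (1 - sum(w)) / n_clusters
  } else {
    w <- weights
    n_clusters <- length(w)
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  if (is.null(mu)) {
    if (n_clusters > 1024) stop("cannot draw distinct mean vectors")
    repeat {
      mu <- matrix(sample(c(0, 8), n_clusters * dim, replace = TRUE), n_clusters)
      if (!anyDuplicated(mu)) break
    }
  }
  samples <- vector("list", n_samples)
  labels <- vector("list", n_samples)
  mk <- sprintf("V%d", seq_len(dim))
  for (s in seq_len(n_samples)) {
    d <- draw_mixture_sample(w, mu, n_obs, dim)
    colnames(d$values) <- mk
    sid <- sprintf("sample%02d", s)
    samples[[s]] <- expression_matrix(d$values, mk, sid)
    labels[[s]] <- d$labels
  }
  names(samples) <- names(labels) <- vapply(samples, function(s) s$sample_id, "")
  structure(list(samples = samples, labels = labels, weights = w, mu = mu,
                 seed = seed, n_obs = n_obs, dim = dim),
            class = "simulated_experiment")
}

#' Non-Gaussian marginal transform
#'
#' Applies the elementwise map `gamma(1 + |x/4|)` (the gamma function, not
#' the distribution), producing margins resembling randomized mass-cytometry
#' intensities: 0 maps to 1, 4 to 1, 8 to 2.
#'
#' @param x numeric vector, matrix, or [expression_matrix].
#' @return transformed object of the same shape.
#' @export
transform_nongaussian <- function(x) {
  if (inherits(x, "expression_matrix")) {
    x$values[] <- gamma(1 + abs(x$values / 4))
    return(x)
  }
  gamma(1 + abs(x / 4))
}

#' Simulate the responder benchmark
#'
#' 20 samples of `n_obs` cells from the fixed 125-component design: 10
#' samples are randomly assigned responder status and use the responder
#' weight vector (predictive component doubled to 0.0022); the other 10 use
#' the non-responder vector (predictive weight 0.0011). Component means and
#' labels are shared.
#'
#' @param seed integer seed.
#' @param n_obs cells per sample.
#' @param n_samples total samples (half responders).
#' @param transform apply [transform_nongaussian] to every sample.
#' @return a `simulated_experiment` with additional elements `responder`
#'   (named logical) and `predictive` (component index).
#' @export
simulate_responder_experiment <- function(seed = 1L, n_obs = 25000L,
                                          n_samples = 20L, transform = FALSE) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  dim <- 10L
  k <- 125L
  repeat {
    mu <- matrix(sample(c(0, 8), k * dim, replace = TRUE), k)
    if (!anyDuplicated(mu)) break
  }
  resp <- sample(rep(c(TRUE, FALSE), each = n_samples / 2))
  mk <- sprintf("V%d", seq_len(dim))
  samples <- labels <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    w <- responder_weights(resp[s])
    w <- w / sum(w)
    d <- draw_mixture_sample(w, mu, n_obs, dim)
    colnames(d$values) <- mk
    sid <- sprintf("sample%02d", s)
    em <- expression_matrix(d$values, mk, sid)
    if (transform) em <- transform_nongaussian(em)
    samples[[s]] <- em
    labels[[s]] <- d$labels
  }
  names(samples) <- names(labels) <- vapply(samples, function(s) s$sample_id, "")
  structure(list(samples = samples, labels = labels, mu = mu, seed = seed,
                 n_obs = n_obs, dim = dim,
                 responder = setNames(resp, names(samples)),
                 predictive = predictive_component()),
            class = "simulated_experiment")
}

#' Adjusted Rand index
#'
#' Hubert-Arabie chance-corrected agreement between two labelings, optionally
#' restricted to a subset of positions.
#'
#' @param a,b equal-length label vectors.
#' @param restrict_to optional index vector restricting the comparison.
#' @return ARI (1 for identical partitions, ~0 for independent ones).
#' @export
adjusted_rand_index <- function(a, b, restrict_to = NULL) {
  stopifnot(length(a) == length(b))
  if (!is.null(restrict_to)) { a <- a[restrict_to]; b <- b[restrict_to] }
  tb <- table(a, b)
  if (length(tb) == 1) return(1)
  sij <- sum(choose(tb, 2))
  si <- sum(choose(rowSums(tb), 2))
  sj <- sum(choose(colSums(tb), 2))
  sn <- choose(sum(tb), 2)
  exp_ <- si * sj / sn
  mx <- (si + sj) / 2
  if (mx == exp_) return(0)
  (sij - exp_) / (mx - exp_)
}

#' Top differentially abundant cluster
#'
#' Fits the per-phenotype binomial GLMM with a sample-level random effect and
#' returns the phenotype with the smallest p-value (ties: smaller column
#' index) together with the per-cell binary membership labeling.
#'
#' @param counts samples x phenotypes count matrix with `totals` attribute.
#' @param responder per-sample 0/1 indicator.
#' @param annotations named list: sample -> per-cell annotation labels (used
#'   to build the binary labeling).
#' @return list: `phenotype`, `p_value`, `table` (all fits), `membership`
#'   (named list of per-cell logicals).
#' @export
top_cluster <- function(counts, responder, annotations = NULL) {
  if (ncol(counts) < 2) warning("top_cluster on a single-phenotype matrix")
  da <- differential_abundance(counts, responder)
  ok <- which(!is.na(da$p))
  if (!length(ok)) stop("all differential-abundance fits failed")
  best <- ok[which.min(da$p[ok])]
  ph <- da$phenotype[best]
  membership <- if (!is.null(annotations))
    lapply(annotations, function(l) l == ph)
  list(phenotype = ph, p_value = da$p[best], table = da,
       membership = membership)
}

#' Stratified 5-fold cross-validated AUC
#'
#' Logistic model of class on a single frequency covariate; folds are
#' stratified by class; reports the mean ROC AUC over folds.
#'
#' @param freq per-sample frequency of the candidate cluster.
#' @param responder per-sample 0/1 class.
#' @param seed fold-assignment seed.
#' @param folds number of folds.
#' @return mean AUC in `[0, 1]`.
#' @export
five_fold_cv_auc <- function(freq, responder, seed = 1L, folds = 5L) {
  y <- as.integer(as.logical(responder))
  stopifnot(length(freq) == length(y), length(y) >= folds,
            length(unique(y)) == 2)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in c(0L, 1L)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  aucs <- vapply(seq_len(folds), function(f) {
    tr <- fold != f; te <- !tr
    if (length(unique(y[te])) < 2) return(NA_real_)
    fit <- suppressWarnings(glm(y ~ x, data = data.frame(y = y[tr], x = freq[tr]),
                                family = binomial()))
    pr <- predict(fit, newdata = data.frame(x = freq[te]), type = "response")
    auc_rank(pr, y[te])
  }, 0)
  mean(aucs, na.rm = TRUE)
}

# Wilcoxon rank formulation of the ROC AUC
auc_rank <- function(score, y) {
  r <- rank(score)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
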
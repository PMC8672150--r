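#' Gaussian-mixture clustering benchmark
#'
#' Simulates a multivariate Gaussian mixture experiment, runs the full
#' discovery pipeline, and evaluates the phenotype labeling against the
#' generating component labels: adjusted Rand index over all cells and over
#' the annotated subset (cells carrying a down-selected phenotype), plus the
#' estimated number of phenotypes.
#'
#' @param n_clusters true number of mixture components.
#' @param n_samples,n_obs experiment size.
#' @param transform apply the `gamma(1 + |x/4|)` marginal transform before
#'   analysis.
#' @param seed simulation seed (also drives the pipeline seed).
#' @param config a [pf_config].
#' @return list: `ari_annotated`, `ari_full`, `n_phenotypes`, `n_clusters`,
#'   `coverage` (fraction of cells annotated), and the discovery result.
#' @export
benchmark_gaussian <- function(n_clusters, n_samples = 3L, n_obs = 10000L,
                               transform = FALSE, seed = 1L,
                               config = pf_config(n_trees = 25L)) {
  config$seed <- derive_seed(seed, 1L)
  sim <- simulate_gaussian_experiment(n_clusters, n_samples = n_samples,
                                      n_obs = n_obs, seed = seed)
  samples <- if (transform) lapply(sim$samples, transform_nongaussian) else sim$samples
  res <- run_discover(samples, config = config)
  truth <- unlist(sim$labels[rownames(res$counts)], use.names = FALSE)
  labels <- unlist(res$cell_labels[rownames(res$counts)], use.names = FALSE)
  labels <- restrict_labels(labels, res$phenotypes)
  annotated <- which(labels != unassigned_label())
  list(ari_annotated = adjusted_rand_index(labels, truth, restrict_to = annotated),
       ari_full = adjusted_rand_index(labels, truth),
       n_phenotypes = length(res$phenotypes),
       n_clusters = n_clusters,
       coverage = length(annotated) / length(labels),
       discovery = res)
}

#' Responder-discovery benchmark
#'
#' Simulates the 20-sample responder design (the predictive component's
#' weight is doubled in responders), runs discovery, identifies the top
#' differentially abundant phenotype by per-phenotype binomial GLMM, and
#' scores it by the binary adjusted Rand index against the true predictive
#' component and by stratified 5-fold cross-validated AUC of a logistic
#' model on its frequency.
#'
#' @param seed simulation seed.
#' @param n_obs cells per sample.
#' @param transform apply the non-Gaussian marginal transform.
#' @param config a [pf_config].
#' @return list: `auc`, `ari_top`, `top_phenotype`, `top_p`,
#'   `n_phenotypes`, and the discovery result.
#' @export
benchmark_responder <- function(seed = 1L, n_obs = 25000L, transform = FALSE,
                                config = pf_config(n_trees = 10L)) {
  config$seed <- derive_seed(seed, 2L)
  sim <- simulate_responder_experiment(seed = seed, n_obs = n_obs,
                                       transform = transform)
  res <- run_discover(sim$samples, config = config)
  resp <- as.numeric(sim$responder[rownames(res$counts)])
  tc <- top_cluster(res$counts, resp, annotations = res$cell_labels)
  truth_bin <- unlist(lapply(sim$labels[rownames(res$counts)],
                             function(l) l == sim$predictive), use.names = FALSE)
  est_bin <- unlist(tc$membership[rownames(res$counts)], use.names = FALSE)
  freq <- res$counts[, tc$phenotype] / attr(res$counts, "totals")
  list(auc = five_fold_cv_auc(freq, resp, seed = derive_seed(seed, 3L)),
       ari_top = adjusted_rand_index(est_bin, truth_bin),
       top_phenotype = tc$phenotype, top_p = tc$p_value,
       n_phenotypes = length(res$phenotypes),
       discovery = res)
}
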
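#' Pipeline configuration
#'
#' Collects the tuning parameters of the discovery pipeline with the
#' method's default settings: dip threshold 0.25, minimum gateable
#' population 500 (annotation forest) and leaf floor 25 (discovery forest),
#' gating strategies of at most 3 markers and 4 gates per marker,
#' depth-score selection at the median with threshold 0.01, automatic
#' occurrence threshold, and 100 discovery trees per unit.
#'
#' @param dip_threshold dip p-value below which unimodality is rejected.
#' @param min_events smallest population gated in the annotation forest.
#' @param min_leaf smallest splittable population in discovery trees.
#' @param max_depth markers per annotation-forest strategy.
#' @param max_gates maximum gates per marker and node.
#' @param ts_scale taut-string tube scale factor.
#' @param score_quantile depth-score selection quantile (0.5 = median).
#' @param score_threshold depth-score selection threshold.
#' @param occurrence_threshold `"auto"` (GCM elbow) or an integer.
#' @param n_trees discovery trees per experimental unit.
#' @param seed master seed; per-unit seeds are derived deterministically.
#' @param boundary_overrides named list marker -> `c(low, high)` replacing
#'   the default marker bounds (e.g. FMO-informed lower bounds).
#' @param supervised named list marker -> `list(count =, locations =)`
#'   supervised boundary settings bypassing the standardization vote.
#' @return a `pf_config` list.
#' @export
pf_config <- function(dip_threshold = 0.25, min_events = 500L, min_leaf = 25L,
                      max_depth = 3L, max_gates = 4L, ts_scale = 0.4,
                      score_quantile = 0.5, score_threshold = 0.01,
                      occurrence_threshold = "auto", n_trees = 100L,
                      seed = 1L, boundary_overrides = NULL,
                      supervised = NULL) {
  structure(list(dip_threshold = dip_threshold, min_events = as.integer(min_events),
                 min_leaf = as.integer(min_leaf), max_depth = as.integer(max_depth),
                 max_gates = as.integer(max_gates), ts_scale = ts_scale,
                 score_quantile = score_quantile, score_threshold = score_threshold,
                 occurrence_threshold = occurrence_threshold,
                 n_trees = as.integer(n_trees), seed = as.integer(seed),
                 boundary_overrides = boundary_overrides,
                 supervised = supervised),
            class = "pf_config")
}

apply_boundary_overrides <- function(bounds, overrides) {
  for (m in names(overrides)) {
    if (!m %in% colnames(bounds)) stop("boundary override for unknown marker: ", m)
    bounds[, m] <- overrides[[m]]
  }
  bounds
}

#' Run the full discovery pipeline
#'
#' Executes, in order: marker-bound computation, per-unit annotation
#' forests, depth scoring, marker selection, per-unit boundary estimation,
#' cross-unit threshold standardization, per-unit discovery forests,
#' per-cell annotation, phenotype down-selection by occurrence, and count
#' matrix construction.
#'
#' @param samples list of [expression_matrix] (or a `simulated_experiment`).
#' @param design optional [experiment_design]; default: one unit per sample.
#' @param config a [pf_config].
#' @param bounds optional marker boundary matrix.
#' @param markers optional fixed marker set, bypassing depth-score selection
#'   (used for targeted threshold generation on validation data).
#' @param discovery grow discovery forests and build the count matrix; set
#'   to `FALSE` to stop after threshold standardization (the targeted
#'   validation workflow).
#' @param verbose print one line per unit and stage.
#' @return a `pf_discovery` result: `counts`, `phenotypes`, `occurrence`,
#'   `occurrence_threshold`, `selected_markers`, `boundary_spec`,
#'   `depth_scores`, per-sample `cell_labels`/`cell_levels`, `bounds`.
#' @export
run_discover <- function(samples, design = NULL, config = pf_config(),
                         bounds = NULL, markers = NULL, discovery = TRUE,
                         verbose = FALSE) {
  if (inherits(samples, "simulated_experiment")) samples <- samples$samples
  stopifnot(length(samples) >= 1)
  sample_ids <- vapply(samples, function(s) s$sample_id, "")
  names(samples) <- sample_ids
  if (is.null(design))
    design <- experiment_design(sample_ids,
                                unit = vapply(samples, function(s) s$unit_id, ""))
  active <- attr(design, "active_markers") %||% samples[[1]]$markers

  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(bounds)) bounds <- default_boundary_matrix(samples)
  bounds <- apply_boundary_overrides(bounds, config$boundary_overrides)

  units <- unique(design$unit)
  unit_ems <- lapply(units, function(u) {
    ss <- samples[design$sample[design$unit == u]]
    ss <- lapply(ss, function(s) { s$unit_id <- u; s })
    concatenate_unit(ss)
  })
  names(unit_ems) <- units

  forests <- scores <- setNames(vector("list", length(units)), units)
  for (u in units) {
    say("unit %s: annotation forest", u)
    forests[[u]] <- grow_annotation_forest(
      unit_ems[[u]], active, bounds,
      dip_threshold = config$dip_threshold, min_events = config$min_events,
      max_depth = config$max_depth, max_gates = config$max_gates,
      ts_scale = config$ts_scale)
    scores[[u]] <- depth_scores(forests[[u]])
  }

  selected <- markers %||% select_markers(scores, prob = config$score_quantile,
                                          threshold = config$score_threshold)
  if (!length(selected))
    stop("no marker exceeded the depth-score threshold; nothing to annotate")
  say("selected markers: %s", paste(selected, collapse = ", "))

  unit_bnds <- lapply(units, function(u) {
    bl <- lapply(selected, function(m)
      estimate_unit_boundaries(forests[[u]], scores[[u]], m))
    setNames(lapply(bl, function(b) if (is.null(b)) NULL else b$locations), selected)
  })
  names(unit_bnds) <- units
  hierarchy <- setNames(
    design$hierarchy[match(units, design$unit)], units)
  spec <- standardize_all(unit_bnds, selected, hierarchy = hierarchy,
                          overrides = config$supervised)

  discoveries <- setNames(vector("list", length(units)), units)
  if (discovery) for (i in seq_along(units)) {
    u <- units[i]
    say("unit %s: discovery forest", u)
    discoveries[[u]] <- discover_unit(
      unit_ems[[u]], selected, bounds, unit_thresholds(spec, u),
      n_trees = config$n_trees, dip_threshold = config$dip_threshold,
      min_leaf = config$min_leaf, max_gates = config$max_gates,
      ts_scale = config$ts_scale, seed = derive_seed(config$seed, i))
  }

  cell_labels <- cell_levels <- setNames(vector("list", length(samples)),
                                         sample_ids)
  for (s in sample_ids) {
    u <- design$unit[design$sample == s]
    ann <- annotate_cells(samples[[s]]$values[, selected, drop = FALSE],
                          unit_thresholds(spec, u))
    cell_labels[[s]] <- ann$labels
    cell_levels[[s]] <- ann$levels
  }

  if (discovery) {
    occ <- occurrence_counts(lapply(discoveries, `[[`, "phenotypes"))
    thr <- if (identical(config$occurrence_threshold, "auto"))
      gcm_elbow_threshold(occ, n_samples = length(samples))
    else as.integer(config$occurrence_threshold)
    phenotypes <- names(occ)[occ >= thr]
    counts <- build_count_matrix(cell_labels, phenotypes)
  } else {
    occ <- integer(0); thr <- NA_integer_; phenotypes <- character(0)
    counts <- build_count_matrix(cell_labels, character(0))
  }

  structure(list(counts = counts, phenotypes = phenotypes, occurrence = occ,
                 occurrence_threshold = thr, selected_markers = selected,
                 boundary_spec = spec, depth_scores = scores,
                 cell_labels = cell_labels, cell_levels = cell_levels,
                 bounds = bounds, design = design, config = config),
            class = "pf_discovery")
}

#' @export
print.pf_discovery <- function(x, ...) {
  cat(sprintf("<pf_discovery> %d sample(s), %d selected marker(s), %d phenotype(s) (occurrence >= %d)\n",
              nrow(x$counts), length(x$selected_markers),
              length(x$phenotypes), x$occurrence_threshold))
  invisible(x)
}

#' Write discovery artifacts to a directory
#'
#' Counts, standardized thresholds, depth scores and per-cell annotations as
#' CSV, plus a JSON run manifest (parameters, seeds, stage outputs).
#'
#' @param res a [run_discover] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_discovery <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm <- data.frame(sample = rownames(res$counts), res$counts,
                   total = attr(res$counts, "totals"), check.names = FALSE)
  utils::write.csv(cm, file.path(dir, "counts.csv"), row.names = FALSE)
  utils::write.csv(boundary_spec_table(res$boundary_spec),
                   file.path(dir, "thresholds.csv"), row.names = FALSE)
  ds <- do.call(rbind, lapply(names(res$depth_scores), function(u)
    cbind(unit = u, res$depth_scores[[u]])))
  utils::write.csv(ds, file.path(dir, "depth_scores.csv"), row.names = FALSE)
  for (s in names(res$cell_labels))
    utils::write.csv(
      data.frame(annotation = restrict_labels(res$cell_labels[[s]], res$phenotypes)),
      file.path(dir, sprintf("annotations_%s.csv", s)), row.names = FALSE)
  manifest <- list(
    package = "phenoforest",
    version = as.character(utils::packageVersion("phenoforest")),
    created = format(Sys.time(), tz = "UTC"),
    config = res$config[setdiff(names(res$config), c("boundary_overrides", "supervised"))],
    selected_markers = res$selected_markers,
    occurrence_threshold = res$occurrence_threshold,
    occurrence_counts = as.list(res$occurrence),
    n_phenotypes = length(res$phenotypes))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Simulate a benchmark experiment and write it to disk
#'
#' Writes one CSV per simulated sample plus a `_labels.csv` sidecar with the
#' generating component of every cell (and a `responder.csv` table for the
#' responder design).
#'
#' @param out output directory.
#' @param responder simulate the fixed 125-component responder design
#'   instead of the reference-weight mixture.
#' @param n_clusters,n_samples,n_obs,seed,transform generator settings (see
#'   [simulate_gaussian_experiment] and [simulate_responder_experiment]).
#' @return the `simulated_experiment`, invisibly.
#' @export
run_simulate <- function(out, responder = FALSE, n_clusters = 5L,
                         n_samples = 10L, n_obs = 25000L, seed = 1L,
                         transform = FALSE) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  sim <- if (responder) {
    simulate_responder_experiment(seed = seed, n_obs = n_obs,
                                  transform = transform)
  } else {
    s <- simulate_gaussian_experiment(n_clusters, n_samples = n_samples,
                                      n_obs = n_obs, seed = seed)
    if (transform) s$samples <- lapply(s$samples, transform_nongaussian)
    s
  }
  for (s in names(sim$samples)) {
    utils::write.csv(sim$samples[[s]]$values,
                     file.path(out, paste0(s, ".csv")), row.names = FALSE)
    utils::write.csv(data.frame(label = sim$labels[[s]]),
                     file.path(out, paste0(s, "_labels.csv")), row.names = FALSE)
  }
  if (!is.null(sim$responder))
    utils::write.csv(data.frame(sample = names(sim$responder),
                                responder = as.integer(sim$responder)),
                     file.path(out, "responder.csv"), row.names = FALSE)
  invisible(sim)
}

#' Targeted phenotype extraction on (new) samples
#'
#' Generates data-driven annotation thresholds for the requested markers on
#' the given samples (annotation forest + standardization only), annotates
#' every cell, and extracts counts of the pre-specified targets.
#'
#' @param samples list of [expression_matrix].
#' @param targets list of partial phenotypes: each a named list
#'   marker -> accepted level labels.
#' @param design optional [experiment_design].
#' @param config a [pf_config].
#' @param markers markers to threshold (default: union of target markers).
#' @return integer matrix samples x targets (attribute `totals`), plus the
#'   boundary spec in attribute `boundary_spec`.
#' @export
run_target <- function(samples, targets, design = NULL, config = pf_config(),
                       markers = NULL) {
  if (is.null(markers))
    markers <- unique(unlist(lapply(targets, names)))
  res <- run_discover(samples, design = design, config = config,
                      markers = markers, discovery = FALSE)
  sample_ids <- names(res$cell_labels)
  level_sets <- lapply(sample_ids, function(s)
    list(labels = res$cell_labels[[s]], levels = res$cell_levels[[s]]))
  names(level_sets) <- sample_ids
  thr_by_sample <- lapply(sample_ids, function(s) {
    u <- res$design$unit[res$design$sample == s]
    unit_thresholds(res$boundary_spec, u)
  })
  names(thr_by_sample) <- sample_ids
  out <- target_phenotypes(level_sets, thr_by_sample, targets)
  attr(out, "boundary_spec") <- res$boundary_spec
  out
}
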
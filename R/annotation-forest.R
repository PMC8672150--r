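#' Grow the annotation forest of an experimental unit
#'
#' Exhaustively explores all "reasonable" gating strategies of depth at most
#' `max_depth`: at every node, each active marker not already on the path is
#' dip-tested (on events strictly within its marker bounds); markers with
#' dip p-value below `dip_threshold` are gated at the antimode midpoints of
#' their taut-string density, provided this yields at most `max_gates` gates.
#' Child populations are the event subsets between consecutive gates; events
#' flagged outside the marker bounds are assigned to the extreme children but
#' excluded from all dip testing and density estimation. Recursion stops at
#' `max_depth`, when no marker is multimodal, or when a node holds fewer than
#' `min_events` events.
#'
#' @param em an [expression_matrix] holding one experimental unit.
#' @param active_markers markers eligible for gating.
#' @param bounds marker boundary matrix (see [default_boundary_matrix]).
#' @param dip_threshold dip p-value below which unimodality is rejected.
#' @param min_events smallest population that may be gated.
#' @param max_depth maximum number of markers per gating strategy.
#' @param max_gates maximum gates per marker and node; markers whose taut
#'   string yields more are treated as non-gateable at that node.
#' @param ts_scale taut-string tube scale factor (see [taut_string_density]).
#' @return object of class `annotation_forest`: gating records, per-depth
#'   gating counts `d`, per-marker effective root sizes `Pm`.
#' @export
grow_annotation_forest <- function(em, active_markers = em$markers, bounds,
                                   dip_threshold = 0.25, min_events = 500L,
                                   max_depth = 3L, max_gates = 4L,
                                   ts_scale = 0.4) {
  stopifnot(inherits(em, "expression_matrix"))
  missing_m <- setdiff(active_markers, em$markers)
  if (length(missing_m)) stop("active markers absent from panel: ",
                              paste(missing_m, collapse = ", "))
  vals <- em$values
  n_root <- nrow(vals)
  Pm <- vapply(active_markers, function(m)
    effective_sample_size(vals[, m], bounds[, m]), 0L)
  acc <- new.env(parent = emptyenv())
  acc$records <- vector("list", 256L); acc$k <- 0L

  push <- function(rec) {
    k <- acc$k + 1L
    if (k > length(acc$records)) acc$records <- c(acc$records, vector("list", length(acc$records)))
    acc$records[[k]] <- rec
    acc$k <- k
  }

  recurse <- function(idx, path_markers, path_ps, depth) {
    if (depth >= max_depth || length(idx) < min_events) return(invisible())
    mk <- setdiff(active_markers, path_markers)
    sc <- node_scan(vals, idx, mk, bounds, dip_threshold, ts_scale, max_gates)
    for (m in mk) {
      gates <- sc$gates[[m]]
      if (!length(gates)) next
      push(list(marker = m, depth = depth, alphas = c(path_ps, sc$p[[m]]),
                n_eff = sc$n_eff[[m]], gates = gates))
      grp <- findInterval(vals[idx, m], gates)
      for (g in 0:length(gates)) {
        child <- idx[grp == g]
        if (length(child) >= min_events)
          recurse(child, c(path_markers, m), c(path_ps, sc$p[[m]]), depth + 1L)
      }
    }
    invisible()
  }
  recurse(seq_len(n_root), character(0), numeric(0), 0L)

  records <- acc$records[seq_len(acc$k)]
  depths <- vapply(records, function(r) r$depth, 0L)
  d <- vapply(0:(max_depth - 1L), function(q) sum(depths == q), 0L)
  structure(list(records = records, d = d, Pm = Pm, n_root = n_root,
                 unit_id = em$unit_id, active_markers = active_markers,
                 params = list(dip_threshold = dip_threshold,
                               min_events = min_events, max_depth = max_depth,
                               max_gates = max_gates, ts_scale = ts_scale)),
            class = "annotation_forest")
}

#' @export
print.annotation_forest <- function(x, ...) {
  cat(sprintf("<annotation_forest> unit '%s': %d gating records (by depth: %s)\n",
              x$unit_id, length(x$records), paste(x$d, collapse = "/")))
  invisible(x)
}

#' Summarize an annotation forest for serialization
#' @param forest an [grow_annotation_forest] result.
#' @return list (JSON-ready): unit, root size, gating counts per depth, and
#'   the gated markers with record counts.
#' @export
forest_summary <- function(forest) {
  stopifnot(inherits(forest, "annotation_forest"))
  mk <- vapply(forest$records, `[[`, "", "marker")
  list(unit = forest$unit_id, n_root = forest$n_root,
       gatings_by_depth = as.list(setNames(as.integer(forest$d),
                                           paste0("depth", seq_along(forest$d)))),
       gated_markers = as.list(table(mk)))
}

#' Gating-strategy quality
#'
#' Quality of the strategy leading to a gated node: the product of
#' `1 - alpha` over the dip p-values along the strategy (root first, the
#' node's own p-value last). A grandchild gated after three ancestral
#' p-values of 0.25 scores `0.75^3 = 27/64`.
#'
#' @param dip_pvalues numeric vector of 1 to 3 dip p-values in `[0, 1]`.
#' @return quality in `[0, 1]`.
#' @export
node_quality <- function(dip_pvalues) {
  if (length(dip_pvalues) < 1 || length(dip_pvalues) > 3)
    stop("a gating strategy carries 1 to 3 dip p-values")
  if (any(!is.finite(dip_pvalues)) || any(dip_pvalues < 0 | dip_pvalues > 1))
    stop("dip p-values must lie in [0, 1]")
  prod(1 - dip_pvalues)
}

#' Depth scores of an annotation forest
#'
#' For each marker, sums the per-record weight `omega = Q * P * D` over all
#' nodes where the marker's unimodality was rejected: `Q` the strategy
#' quality ([node_quality]), `P` the node's effective size relative to the
#' marker's effective root size, and `D = 1/d_i` the factorial depth penalty
#' (`d_i` = number of gatings at that depth in the whole forest). Raw scores
#' are normalized by the per-unit maximum so the best-separated marker scores
#' exactly 1.
#'
#' @param forest an [grow_annotation_forest] result.
#' @return object of class `depth_score_table`: data.frame with columns
#'   `marker`, `raw`, `ds`, attribute `d`, and per-record omegas for
#'   downstream boundary estimation.
#' @export
depth_scores <- function(forest) {
  stopifnot(inherits(forest, "annotation_forest"))
  mk <- forest$active_markers
  raw <- setNames(numeric(length(mk)), mk)
  omega <- numeric(length(forest$records))
  for (i in seq_along(forest$records)) {
    r <- forest$records[[i]]
    Q <- prod(1 - r$alphas)
    P <- r$n_eff / forest$Pm[[r$marker]]
    D <- 1 / forest$d[r$depth + 1L]
    omega[i] <- Q * P * D
    raw[r$marker] <- raw[r$marker] + omega[i]
  }
  mx <- if (length(raw) && max(raw) > 0) max(raw) else NA_real_
  ds <- if (is.na(mx)) setNames(rep(0, length(mk)), mk) else raw / mx
  structure(data.frame(marker = mk, raw = as.numeric(raw), ds = as.numeric(ds),
                       stringsAsFactors = FALSE),
            class = c("depth_score_table", "data.frame"),
            d = forest$d, omega = omega, unit_id = forest$unit_id,
            all_zero = is.na(mx))
}

#' Select markers by cross-unit depth-score quantile
#'
#' A marker is retained for discovery and annotation when the chosen
#' empirical quantile of its normalized depth scores across experimental
#' units exceeds the threshold.
#'
#' @param score_tables list of [depth_scores] results (one per unit).
#' @param prob quantile level (default median).
#' @param threshold depth-score selection threshold.
#' @return character vector of selected markers (panel order).
#' @export
select_markers <- function(score_tables, prob = 0.5, threshold = 0.01) {
  stopifnot(length(score_tables) >= 1)
  mk <- score_tables[[1]]$marker
  dsm <- vapply(score_tables, function(t) {
    stopifnot(identical(t$marker, mk))
    t$ds
  }, numeric(length(mk)))
  dsm <- matrix(dsm, nrow = length(mk))
  qs <- apply(dsm, 1, quantile, probs = prob, names = FALSE)
  mk[qs > threshold]
}

#' Annotation boundaries of one marker in one unit
#'
#' Gating records for the marker are partitioned by their taut-string gate
#' count; the count with the maximal total omega mass wins, and each boundary
#' is the omega-weighted average of the corresponding gate location over the
#' winning records.
#'
#' @param forest an [grow_annotation_forest] result.
#' @param scores the matching [depth_scores] result.
#' @param marker marker name.
#' @return list with `marker`, `n_gates`, `locations`, `mass`, or `NULL`
#'   when the marker was never gated in this unit (a missing-boundaries
#'   record consumed by standardization).
#' @export
estimate_unit_boundaries <- function(forest, scores, marker) {
  omega <- attr(scores, "omega")
  sel <- which(vapply(forest$records, function(r) r$marker == marker, TRUE))
  if (!length(sel)) return(NULL)
  ng <- vapply(forest$records[sel], function(r) length(r$gates), 0L)
  mass <- tapply(omega[sel], ng, sum)
  j <- as.integer(names(mass)[which.max(mass)])  # ties: which.max takes first (smaller j)
  grp <- sel[ng == j]
  w <- omega[grp]
  gmat <- t(vapply(forest$records[grp], function(r) r$gates, numeric(j)))
  if (j == 1) gmat <- matrix(gmat, ncol = 1)
  locs <- as.numeric(colSums(gmat * w) / sum(w))
  list(marker = marker, n_gates = j, locations = locs, mass = max(mass))
}
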
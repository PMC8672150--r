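#' Level labels for a marker with k annotation boundaries
#'
#' One boundary splits expression into `-` / `+`; two into `-` / `dim` /
#' `bright`; three and four boundaries extend the ordinal scale.
#'
#' @param k number of boundaries (1-4).
#' @return character vector of k + 1 ordered level labels.
#' @export
level_labels <- function(k) {
  switch(k,
         c("-", "+"),
         c("-", "dim", "bright"),
         c("-", "dim", "bright", "vbright"),
         c("-", "low", "dim", "bright", "vbright"),
         stop("1 to 4 boundaries supported"))
}

#' Map expression values to level indices
#'
#' The level is the interval containing the value; a value exactly on a
#' boundary is assigned the lower level.
#'
#' @param x numeric vector.
#' @param gates sorted boundary locations.
#' @return integer level indices in `1:(length(gates)+1)`.
#' @keywords internal
#' @noRd
level_index <- function(x, gates) {
  idx <- rep(1L, length(x))
  for (g in gates) idx <- idx + (x > g)
  idx
}

#' Grow one randomized partition tree
#'
#' Recursive splitting as in the annotation forest but with no depth limit
#' and a 25-event leaf floor: at every node the marker to gate is drawn
#' uniformly at random from the multimodal candidates (dip p-value below the
#' threshold, gateable by the taut string). The randomness is what makes a
#' forest of such trees diverse. A node with no multimodal marker, or fewer
#' than `min_leaf` events, becomes a leaf.
#'
#' @param em an [expression_matrix] (one experimental unit).
#' @param markers the selected markers.
#' @param bounds marker boundary matrix.
#' @param dip_threshold,max_gates,ts_scale as in [grow_annotation_forest].
#' @param min_leaf smallest splittable population.
#' @return list of leaves, each an integer vector of event indices; leaves
#'   partition the unit's events. Uses R's RNG stream (seed upstream for
#'   reproducibility).
#' @export
grow_partition_tree <- function(em, markers, bounds, dip_threshold = 0.25,
                                min_leaf = 25L, max_gates = 4L, ts_scale = 0.4) {
  vals <- em$values
  leaves <- list()
  recurse <- function(idx, avail) {
    if (length(idx) >= min_leaf && length(avail)) {
      # visiting markers in a uniformly random order and gating the first
      # multimodal, gateable one is distributionally identical to choosing
      # uniformly among all such candidates, at a fraction of the dip tests
      ord <- if (length(avail) > 1) sample(avail) else avail
      sc <- node_scan(vals, idx, ord, bounds, dip_threshold, ts_scale,
                      max_gates, lazy = TRUE)
      hit <- which(lengths(sc$gates) > 0)
      if (length(hit)) {
        m <- ord[hit[1]]
        gates <- sc$gates[[hit[1]]]
        grp <- findInterval(vals[idx, m], gates)
        for (g in 0:length(gates)) {
          child <- idx[grp == g]
          if (length(child)) recurse(child, setdiff(avail, m))
        }
        return(invisible())
      }
    }
    leaves[[length(leaves) + 1L]] <<- idx
    invisible()
  }
  recurse(seq_len(nrow(vals)), markers)
  leaves
}

#' Shape score of a candidate leaf
#'
#' Rewards leaves whose margins look like a single homogeneous population:
#' `score = n * prod_m u_m` with
#' `u_m = p_dip * exp(-|tau3|) * exp(-|tau4 - 0.1226|)`, where `p_dip` is the
#' margin's dip p-value and `tau3`, `tau4` its trimmed (trim = 1) sample
#' L-skewness and L-kurtosis; 0.1226 is the L-kurtosis of the Gaussian, the
#' reference for a homogeneous margin. Margins with fewer than 5 usable
#' events give score 0.
#'
#' @param leaf_values numeric matrix (leaf cells x selected markers).
#' @return nonnegative score.
#' @export
shape_score <- function(leaf_values) {
  n <- nrow(leaf_values)
  if (is.null(n) || n < 5L) return(0)
  u <- 1
  for (j in seq_len(ncol(leaf_values))) {
    x <- leaf_values[, j]
    p <- if (n >= 4) tryCatch(dip_test(x)$p_value, error = function(e) 0) else 0
    tl <- trimmed_lmoment_ratios(x)
    if (anyNA(tl)) return(0)
    u <- u * p * exp(-abs(tl[["tau3"]])) * exp(-abs(tl[["tau4"]] - 0.1226))
  }
  n * u
}

#' Select a disjoint set of leaves across a discovery forest
#'
#' Greedy weighted set packing: leaves are sorted by shape score (ties:
#' larger leaf, then earlier tree/leaf id) and accepted when disjoint from
#' all previously accepted leaves. Accepted leaves never share a cell;
#' events left uncovered stay unassigned at leaf level.
#'
#' @param leaves list of integer index vectors (all trees' leaves, pooled).
#' @param scores numeric vector of shape scores aligned with `leaves`.
#' @param n_events number of events in the unit.
#' @return integer vector: indices (into `leaves`) of the accepted leaves.
#' @export
select_leaves <- function(leaves, scores, n_events) {
  stopifnot(length(leaves) == length(scores))
  sizes <- lengths(leaves)
  ord <- order(-scores, -sizes, seq_along(leaves))
  taken <- logical(n_events)
  keep <- integer(0)
  for (i in ord) {
    li <- leaves[[i]]
    if (!any(taken[li])) {
      taken[li] <- TRUE
      keep <- c(keep, i)
    }
  }
  keep
}

#' Annotate a leaf against standardized thresholds
#'
#' Each selected marker's level is the interval (with respect to the unit's
#' reconciled boundaries) containing the leaf's margin median; a median
#' exactly on a boundary takes the lower level.
#'
#' @param leaf_values numeric matrix (leaf cells x selected markers).
#' @param thresholds named list marker -> boundary locations for the leaf's
#'   unit (see [unit_thresholds]).
#' @return a phenotype annotation string, e.g. `"CD4- CD8+"`.
#' @export
annotate_leaf <- function(leaf_values, thresholds) {
  mk <- colnames(leaf_values)
  stopifnot(all(mk %in% names(thresholds)))
  lv <- vapply(mk, function(m) {
    g <- thresholds[[m]]
    level_labels(length(g))[level_index(median(leaf_values[, m]), g)]
  }, "")
  paste0(mk, lv, collapse = " ")
}

#' Annotate every cell against standardized thresholds
#'
#' Direct per-marker thresholding of each cell, independent of leaf
#' membership: every cell of every sample receives a full phenotype label.
#'
#' @param values numeric matrix (cells x selected markers).
#' @param thresholds named list marker -> boundary locations.
#' @return list with `labels` (character per cell) and `levels` (integer
#'   matrix of per-marker level indices).
#' @export
annotate_cells <- function(values, thresholds) {
  mk <- colnames(values)
  stopifnot(all(mk %in% names(thresholds)))
  lev <- matrix(0L, nrow(values), length(mk), dimnames = list(NULL, mk))
  parts <- matrix("", nrow(values), length(mk))
  for (j in seq_along(mk)) {
    g <- thresholds[[mk[j]]]
    li <- level_index(values[, mk[j]], g)
    lev[, j] <- li
    parts[, j] <- paste0(mk[j], level_labels(length(g))[li])
  }
  labels <- do.call(paste, c(split(parts, col(parts)), sep = " "))
  list(labels = labels, levels = lev)
}

#' Discover phenotypes in one experimental unit
#'
#' Grows `n_trees` randomized partition trees, scores every leaf, selects a
#' disjoint high-scoring subset across trees, and annotates the selected
#' leaves against the unit's standardized thresholds. The unit's discovered
#' phenotype list is the set of distinct annotations of its selected leaves.
#'
#' @inheritParams grow_partition_tree
#' @param thresholds named list marker -> reconciled boundary locations.
#' @param n_trees number of partition trees.
#' @param seed integer seed making the forest reproducible.
#' @return list with `phenotypes` (character), `selected` (list of leaf index
#'   vectors), `leaf_annotations` (aligned with `selected`).
#' @export
discover_unit <- function(em, markers, bounds, thresholds, n_trees = 100L,
                          dip_threshold = 0.25, min_leaf = 25L,
                          max_gates = 4L, ts_scale = 0.4, seed = 1L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  vals <- em$values[, markers, drop = FALSE]
  all_leaves <- list()
  for (t in seq_len(n_trees)) {
    lv <- grow_partition_tree(em, markers, bounds, dip_threshold,
                              min_leaf, max_gates, ts_scale)
    all_leaves <- c(all_leaves, lv)
  }
  scores <- vapply(all_leaves, function(idx)
    shape_score(vals[idx, , drop = FALSE]), 0)
  keep <- select_leaves(all_leaves, scores, nrow(vals))
  selected <- all_leaves[keep]
  stopifnot(anyDuplicated(unlist(selected)) == 0L)  # leaves share no cells
  ann <- vapply(selected, function(idx)
    annotate_leaf(vals[idx, , drop = FALSE], thresholds), "")
  list(phenotypes = unique(ann), selected = selected, leaf_annotations = ann)
}
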
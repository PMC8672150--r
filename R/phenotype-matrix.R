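#' Cross-unit phenotype occurrence counts
#'
#' Phenotypes are matched across experimental units by exact equality of
#' their annotation strings; each unit contributes at most once per
#' phenotype.
#'
#' @param phenotype_lists list (one element per unit) of character vectors of
#'   discovered phenotypes.
#' @return named integer vector: phenotype -> number of units.
#' @export
occurrence_counts <- function(phenotype_lists) {
  tb <- table(unlist(lapply(phenotype_lists, unique)))
  setNames(as.integer(tb), names(tb))
}

#' Occurrence threshold from the greatest convex minorant elbow
#'
#' With 4 or fewer samples every discovered phenotype is kept (threshold 1).
#' Otherwise phenotypes with occurrence between
#' `phenoMin = max(2, 0.05 n)` and `phenoMax = min(n - 1, 0.95 n)` form an
#' occurrence curve (occurrence value -> number of phenotypes, normalized);
#' its greatest convex minorant is computed and the threshold is the knot
#' maximizing the vertical distance to the chord joining the curve ends.
#'
#' @param occ named integer vector from [occurrence_counts].
#' @param n_samples number of samples in the experiment.
#' @return integer occurrence threshold (phenotypes kept when occurrence is
#'   greater than or equal to it).
#' @export
gcm_elbow_threshold <- function(occ, n_samples) {
  if (n_samples <= 4) return(1L)
  pheno_min <- max(2, 0.05 * n_samples)
  pheno_max <- min(n_samples - 1, 0.95 * n_samples)
  xs <- seq.int(ceiling(pheno_min), floor(pheno_max))
  if (!length(xs) || !any(occ >= pheno_min & occ <= pheno_max)) {
    return(as.integer(ceiling(pheno_min)))   # empty restricted range
  }
  ys <- vapply(xs, function(v) sum(occ == v), 0L)
  ys <- ys / sum(ys)
  if (length(xs) == 1) return(as.integer(xs))
  # greatest convex minorant = lower convex hull of the curve points
  hull <- 1L
  for (i in 2:length(xs)) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      if ((ys[b] - ys[a]) * (xs[i] - xs[a]) >= (ys[i] - ys[a]) * (xs[b] - xs[a]))
        hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  gcm_y <- approx(xs[hull], ys[hull], xout = xs, ties = "ordered")$y
  chord <- ys[1] + (ys[length(ys)] - ys[1]) * (xs - xs[1]) / (xs[length(xs)] - xs[1])
  gaps <- (chord - gcm_y)[hull]
  as.integer(xs[hull][which.max(gaps)])
}

#' Build the sample-by-phenotype count matrix
#'
#' Exact per-sample cell counts of the selected phenotypes, derived from the
#' per-cell annotations. Cells whose annotation is not a selected phenotype
#' contribute to the per-sample totals only; in per-cell exports they carry
#' the reserved non-phenotype label `"0_0_0_0_0"`.
#'
#' @param annotations named list: sample -> character vector of per-cell
#'   annotation labels.
#' @param phenotypes character vector of selected phenotypes (columns).
#' @return object of class `phenotype_counts`: integer matrix
#'   samples x phenotypes with attribute `totals`.
#' @export
build_count_matrix <- function(annotations, phenotypes) {
  samples <- names(annotations)
  m <- matrix(0L, length(samples), length(phenotypes),
              dimnames = list(samples, phenotypes))
  for (s in samples) {
    tb <- table(factor(annotations[[s]], levels = phenotypes))
    m[s, ] <- as.integer(tb)
  }
  structure(m, totals = vapply(annotations, length, 0L),
            class = c("phenotype_counts", class(m)))
}

#' Reserved label for cells outside all selected phenotypes
#' @export
unassigned_label <- function() "0_0_0_0_0"

#' Per-cell labels restricted to the selected phenotypes
#' @param labels character vector of per-cell annotations.
#' @param phenotypes selected phenotypes.
#' @return character vector where non-selected annotations are replaced by
#'   the reserved label `"0_0_0_0_0"`.
#' @export
restrict_labels <- function(labels, phenotypes) {
  ifelse(labels %in% phenotypes, labels, unassigned_label())
}

#' Extract counts of pre-specified phenotypes (targeted approach)
#'
#' Counts, per sample, the cells satisfying every condition of each target.
#' A target is a partial phenotype: a named list mapping a marker to the set
#' of level labels it accepts (e.g. `list("PD-1" = c("dim", "bright"))`),
#' which also expresses coarsened levels when a new dataset has fewer
#' boundaries than discovery had. A target with no conditions matches every
#' cell.
#'
#' @param level_sets named list: sample -> result of [annotate_cells] (the
#'   `levels`/`labels` pair) on the new data.
#' @param thresholds_by_sample named list: sample -> named list of boundary
#'   locations (defines the level vocabulary per marker).
#' @param targets list of targets; each target is a named list
#'   marker -> character vector of accepted levels.
#' @return integer matrix samples x targets with attribute `totals`.
#' @export
target_phenotypes <- function(level_sets, thresholds_by_sample, targets) {
  samples <- names(level_sets)
  tnames <- names(targets) %||% paste0("target", seq_along(targets))
  m <- matrix(0L, length(samples), length(targets),
              dimnames = list(samples, tnames))
  for (s in samples) {
    lv <- level_sets[[s]]$levels
    thr <- thresholds_by_sample[[s]]
    for (t in seq_along(targets)) {
      tg <- targets[[t]]
      ok <- rep(TRUE, nrow(lv))
      for (m_ in names(tg)) {
        if (!m_ %in% names(thr))
          stop("target references marker absent from thresholds: ", m_)
        labs <- level_labels(length(thr[[m_]]))
        want <- match(tg[[m_]], labs)
        if (anyNA(want))
          stop(sprintf("level '%s' undefined for marker '%s' (has %d boundaries)",
                       paste(tg[[m_]][is.na(want)], collapse = ","), m_,
                       length(thr[[m_]])))
        ok <- ok & (lv[, m_] %in% want)
      }
      m[s, t] <- sum(ok)
    }
  }
  structure(m, totals = vapply(level_sets, function(l) nrow(l$levels), 0L))
}

#' Stimulation-differential features
#'
#' For paired stimulated/unstimulated samples: phenotypes whose annotation is
#' negative for the activation marker contribute their frequency in the
#' unstimulated sample; activation-positive phenotypes contribute the
#' stimulated-minus-unstimulated frequency difference.
#'
#' @param counts_stim,counts_unstim [build_count_matrix] results with
#'   identical columns; rows are matched pairs (same subject order).
#' @param activation_marker marker name (e.g. `"CD154"`).
#' @param negative_level label of the marker's negative level (default
#'   `"-"`).
#' @return numeric matrix subjects x phenotypes of features.
#' @export
stim_differential_features <- function(counts_stim, counts_unstim,
                                       activation_marker,
                                       negative_level = "-") {
  stopifnot(identical(colnames(counts_stim), colnames(counts_unstim)))
  if (nrow(counts_stim) != nrow(counts_unstim))
    stop("stimulated and unstimulated samples must be paired")
  fs <- counts_stim / attr(counts_stim, "totals")
  fu <- counts_unstim / attr(counts_unstim, "totals")
  ph <- colnames(counts_stim)
  neg <- vapply(strsplit(ph, " ", fixed = TRUE), function(tt)
    any(tt == paste0(activation_marker, negative_level)), TRUE)
  out <- fu
  out[, !neg] <- fs[, !neg] - fu[, !neg]
  rownames(out) <- rownames(counts_unstim)
  out
}
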
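#' Prepare expression data for an annotation embedding
#'
#' Transforms annotated expression data into a landmark-anchored
#' representation in which every annotation group occupies its own disjoint
#' region per marker, so that a downstream dimensionality reduction (e.g.
#' UMAP) produces islands that match the annotations. Steps: (1) winsorize
#' each marker at its 1st/99th percentiles; (2) add seeded N(0, 0.01) noise
#' to values lying at the winsorization limits (tie-breaking in rare
#' annotation groups); (3) standardize each (annotation group, marker) to
#' mean 0, sd 1 (sd 0 leaves centered zeros); (4) record group extremes;
#' (5) derive one final scale per marker so every group's scaled support
#' fits within half the landmark spacing (times a safety factor); (6)
#' translate each group to the equispaced landmark of its level.
#'
#' @param values numeric matrix (cells x selected markers).
#' @param annotations per-cell annotation labels (every cell annotated).
#' @param levels integer matrix of per-cell level indices (cells x markers),
#'   as returned by [annotate_cells].
#' @param seed seed for the tie-breaking noise.
#' @param spacing landmark spacing per level (default 10).
#' @param safety shrink factor keeping adjacent supports apart (default 0.9).
#' @return list with `transformed` (matrix) and `layout` (per-marker
#'   landmark grid and scale).
#' @export
prepare_annotation_embedding <- function(values, annotations, levels,
                                         seed = 1L, spacing = 10, safety = 0.9) {
  if (anyNA(annotations) || any(!nzchar(annotations)))
    stop("every cell must carry an annotation")
  stopifnot(nrow(values) == length(annotations), nrow(levels) == nrow(values))
  mk <- colnames(values)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  w <- values
  for (j in seq_along(mk)) {
    q <- quantile(w[, j], c(0.01, 0.99), names = FALSE)
    w[, j] <- pmin(pmax(w[, j], q[1]), q[2])
    at_lim <- w[, j] %in% q
    w[at_lim, j] <- w[at_lim, j] + rnorm(sum(at_lim), 0, sqrt(0.01))
  }

  grp <- split(seq_len(nrow(w)), annotations)
  z <- w
  ext <- 0
  for (g in grp) for (j in seq_along(mk)) {
    x <- w[g, j]
    s <- sd(x)
    z[g, j] <- if (length(x) > 1 && s > 0) (x - mean(x)) / s else x - mean(x)
    ext <- max(ext, abs(z[g, j]))
  }
  # one final scale per marker from the largest absolute standardized extreme
  scales <- numeric(length(mk))
  for (j in seq_along(mk)) {
    mj <- max(abs(z[, j]), 1e-12)
    scales[j] <- safety * (spacing / 2) / mj
  }
  out <- z
  for (j in seq_along(mk)) {
    landmark <- (levels[, j] - 1L) * spacing
    out[, j] <- z[, j] * scales[j] + landmark
  }
  layout <- lapply(seq_along(mk), function(j)
    list(marker = mk[j], spacing = spacing, scale = scales[j],
         landmarks = (seq_len(max(levels[, j])) - 1L) * spacing))
  names(layout) <- mk
  list(transformed = out, layout = layout)
}
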
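#' Majority vote on the number of annotation boundaries
#'
#' The standard gate count for a marker is the most frequent count across
#' experimental units; ties favor the smaller count (coarser annotation).
#' A supervised preference can override the vote.
#'
#' @param counts integer vector of per-unit gate counts (units where the
#'   marker was estimated).
#' @param override optional supervised gate count replacing the vote.
#' @return the standard count `k*`.
#' @export
vote_gate_count <- function(counts, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  stopifnot(length(counts) >= 1)
  tb <- table(counts)
  as.integer(names(tb)[which.max(tb)])  # ties: first = smallest count
}

#' Rank-wise median standard boundary locations
#'
#' Given the boundary locations of units conforming to the standard count,
#' the l-th standard is the median over units of the l-th smallest boundary.
#'
#' @param boundary_list list of numeric vectors, each of length `k_star`.
#' @param k_star standard gate count.
#' @return numeric vector of `k_star` standard locations.
#' @export
compute_standards <- function(boundary_list, k_star) {
  boundary_list <- Filter(function(b) length(b) == k_star, boundary_list)
  if (!length(boundary_list))
    stop("no conforming unit to compute standard boundaries from")
  m <- t(vapply(boundary_list, sort, numeric(k_star)))
  if (k_star == 1) m <- matrix(unlist(boundary_list), ncol = 1)
  apply(m, 2, median)
}

#' Reconcile one unit's boundaries against the standards
#'
#' Greedy nearest-distance matching of the unit's boundaries to the standard
#' locations: each standard keeps at most the closest boundary; surplus
#' boundaries are deleted; unmatched standards are imputed at the standard
#' location shifted by the mean signed offset of the unit's matched
#' boundaries (or used directly when nothing matched). The result always has
#' exactly `length(standards)` strictly increasing locations.
#'
#' @param boundaries numeric vector (possibly empty/NULL) of unit boundaries.
#' @param standards numeric vector of standard locations.
#' @return list with `locations` and `provenance` (`"estimated"` or
#'   `"imputed"` per slot) and `n_deleted`.
#' @export
reconcile_unit <- function(boundaries, standards) {
  k <- length(standards)
  b <- sort(as.numeric(boundaries %||% numeric(0)))
  if (!length(b)) {
    return(list(locations = sort(standards),
                provenance = rep("imputed", k), n_deleted = 0L))
  }
  dm <- abs(outer(b, standards, "-"))
  ord <- order(dm)
  used_b <- logical(length(b)); used_s <- logical(k)
  assign_s <- rep(NA_integer_, k)
  for (o in ord) {
    i <- (o - 1) %% length(b) + 1
    j <- (o - 1) %/% length(b) + 1
    if (used_b[i] || used_s[j]) next
    used_b[i] <- TRUE; used_s[j] <- TRUE
    assign_s[j] <- i
  }
  matched <- which(!is.na(assign_s))
  offset <- if (length(matched)) mean(b[assign_s[matched]] - standards[matched]) else 0
  loc <- numeric(k); prov <- character(k)
  for (j in seq_len(k)) {
    if (!is.na(assign_s[j])) {
      loc[j] <- b[assign_s[j]]; prov[j] <- "estimated"
    } else {
      loc[j] <- standards[j] + offset; prov[j] <- "imputed"
    }
  }
  o <- order(loc); loc <- loc[o]; prov <- prov[o]
  if (k > 1) {
    rng <- max(diff(range(c(loc, standards))), abs(loc[1]), 1)
    for (j in 2:k) if (loc[j] <= loc[j - 1]) loc[j] <- loc[j - 1] + 1e-9 * rng
  }
  list(locations = loc, provenance = prov,
       n_deleted = as.integer(sum(!used_b)))
}

#' Standardize annotation boundaries across experimental units
#'
#' Two-pass standardization. The standard gate count per marker is a global
#' majority vote (or supervised override). Pass 1 computes standard locations
#' from conforming units within each imputation-hierarchy class and
#' reconciles that class's units against them. Units in classes with no
#' conforming member are reconciled in pass 2 against standards computed
#' across all units. With the default flat hierarchy the two passes coincide.
#'
#' @param unit_boundaries named list: unit -> (named list: marker ->
#'   numeric gate locations, or NULL when missing).
#' @param markers markers to standardize (the selected markers).
#' @param hierarchy named character vector: unit -> hierarchy class
#'   (default: one shared class).
#' @param overrides optional named list: marker -> list(count=, locations=)
#'   supervised settings; `count` replaces the vote, `locations` replace
#'   estimated standards entirely.
#' @return object of class `boundary_spec`: per marker `k_star`, `standards`,
#'   and per unit reconciled `locations` with `provenance`.
#' @export
standardize_all <- function(unit_boundaries, markers,
                            hierarchy = NULL, overrides = NULL) {
  units <- names(unit_boundaries)
  stopifnot(!is.null(units))
  if (is.null(hierarchy)) hierarchy <- setNames(rep("all", length(units)), units)
  spec <- list()
  for (m in markers) {
    per_unit <- lapply(unit_boundaries, function(u) u[[m]])
    est <- Filter(Negate(is.null), per_unit)
    ov <- overrides[[m]]
    if (!length(est) && is.null(ov))
      stop("marker '", m, "' was never gated in any unit and has no override")
    counts <- vapply(est, length, 0L)
    k_star <- vote_gate_count(counts, override = ov$count %||% NULL)
    global_standards <- if (!is.null(ov$locations)) {
      if (length(ov$locations) != k_star)
        stop("override locations for '", m, "' must have length ", k_star)
      sort(ov$locations)
    } else if (any(counts == k_star)) {
      compute_standards(est, k_star)
    } else {
      # no unit conforms to the (overridden) count: spread the pooled
      # boundary locations into k_star rank groups
      pooled <- sort(unlist(est))
      as.numeric(quantile(pooled, probs = (seq_len(k_star) - 0.5) / k_star,
                          names = FALSE))
    }
    res <- setNames(vector("list", length(units)), units)
    for (cl in unique(hierarchy[units])) {
      cl_units <- units[hierarchy[units] == cl]
      cl_est <- Filter(Negate(is.null), per_unit[cl_units])
      cl_conf <- Filter(function(b) length(b) == k_star, cl_est)
      standards <- if (!is.null(ov$locations)) global_standards
      else if (length(cl_conf)) compute_standards(cl_est, k_star)
      else global_standards                      # pass 2: borrow across classes
      for (u in cl_units) res[[u]] <- reconcile_unit(per_unit[[u]], standards)
    }
    spec[[m]] <- list(marker = m, k_star = k_star,
                      standards = global_standards, units = res)
  }
  structure(list(markers = markers, spec = spec, units = units),
            class = "boundary_spec")
}

#' @export
print.boundary_spec <- function(x, ...) {
  cat(sprintf("<boundary_spec> %d marker(s) x %d unit(s)\n",
              length(x$markers), length(x$units)))
  for (m in x$markers)
    cat(sprintf("  %s: k*=%d standards=(%s)\n", m, x$spec[[m]]$k_star,
                paste(signif(x$spec[[m]]$standards, 4), collapse = ", ")))
  invisible(x)
}

#' Reconciled boundaries of one unit
#' @param spec a [standardize_all] result.
#' @param unit unit identifier.
#' @return named list marker -> numeric locations.
#' @export
unit_thresholds <- function(spec, unit) {
  stopifnot(inherits(spec, "boundary_spec"))
  out <- lapply(spec$spec, function(s) {
    r <- s$units[[unit]]
    if (is.null(r)) stop("unknown unit: ", unit)
    r$locations
  })
  setNames(out, spec$markers)
}

#' Serialize a boundary spec as a data.frame
#' @param spec a [standardize_all] result.
#' @return data.frame (marker, unit, rank, location, provenance).
#' @export
boundary_spec_table <- function(spec) {
  rows <- list()
  for (m in spec$markers) {
    s <- spec$spec[[m]]
    for (u in names(s$units)) {
      r <- s$units[[u]]
      rows[[length(rows) + 1L]] <- data.frame(
        marker = m, unit = u, rank = seq_along(r$locations),
        location = r$locations, provenance = r$provenance,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
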
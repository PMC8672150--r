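#' Construct a per-sample expression matrix
#'
#' The basic data container: one sample's cells-by-markers matrix of
#' (pre-transformed) intensities together with sample and experimental-unit
#' identifiers. Samples sharing a unit identifier are concatenated before
#' discovery and annotation.
#'
#' @param values numeric matrix, cells in rows, markers in columns.
#' @param markers character vector of marker names (defaults to column names).
#' @param sample_id,unit_id identifiers; `unit_id` defaults to `sample_id`.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, markers = colnames(values),
                              sample_id, unit_id = sample_id) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(markers)) stop("marker names are required")
  markers <- as.character(markers)
  if (ncol(values) != length(markers))
    stop("number of markers does not match number of columns")
  if (anyDuplicated(markers)) stop("marker names must be unique")
  if (length(markers) < 2) stop("at least 2 markers are required")
  if (nrow(values) < 1) stop("at least one cell is required")
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("sample '%s': missing value at row %d, column '%s'",
                 sample_id, bad[1], markers[bad[2]]))
  }
  colnames(values) <- markers
  structure(list(values = values, markers = markers,
                 sample_id = as.character(sample_id),
                 unit_id = as.character(unit_id)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> sample '%s' (unit '%s'): %d cells x %d markers\n",
              x$sample_id, x$unit_id, nrow(x$values), length(x$markers)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read one sample from disk
#'
#' Supports delimited text (CSV/TSV with a header row of marker names) and
#' FCS 3.0/3.1 binary files. No compensation or intensity transformation is
#' applied: input is assumed to be pre-transformed upstream. For FCS input,
#' marker names are resolved from the stain keyword (`$PnS`) when present,
#' falling back to the detector name (`$PnN`); a name collision is an error.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"csv"`, `"tsv"`, `"fcs"`. `"auto"` decides
#'   by file extension.
#' @param markers optional character vector selecting (and ordering) a subset
#'   of the file's markers; an unknown marker is an error naming the sample.
#' @param sample_id,unit_id identifiers; default `sample_id` is the file name.
#' @return an [expression_matrix].
#' @export
read_sample <- function(path, format = c("auto", "csv", "tsv", "fcs"),
                        markers = NULL,
                        sample_id = sub("\\.[^.]+$", "", basename(path)),
                        unit_id = sample_id) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext, fcs = "fcs", tsv = "tsv", txt = "tsv", "csv")
  }
  if (format == "fcs") {
    fcs <- read_fcs(path)
    values <- fcs$values
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    values <- as.matrix(df)
    storage.mode(values) <- "double"
    if (anyNA(values)) {
      bad <- which(is.na(values), arr.ind = TRUE)[1, ]
      stop(sprintf("sample '%s': missing or non-numeric value at row %d, column '%s'",
                   sample_id, bad[1], colnames(values)[bad[2]]))
    }
  }
  if (!is.null(markers)) {
    missing_m <- setdiff(markers, colnames(values))
    if (length(missing_m))
      stop(sprintf("sample '%s': markers not present in file: %s",
                   sample_id, paste(missing_m, collapse = ", ")))
    values <- values[, markers, drop = FALSE]
  }
  expression_matrix(values, colnames(values), sample_id, unit_id)
}

#' Describe the experimental design
#'
#' Maps samples to experimental units (samples sharing a unit are concatenated
#' for discovery), optionally assigns each unit an imputation-hierarchy label
#' used during threshold standardization, and carries per-sample covariates
#' for downstream modeling.
#'
#' @param sample character vector of sample identifiers.
#' @param unit experimental unit per sample (default: one unit per sample).
#' @param hierarchy imputation-hierarchy label per unit-row (default: a single
#'   shared class).
#' @param active_markers markers eligible for discovery and annotation.
#' @param starting_population free-text metadata naming the pre-gated
#'   population the analysis starts from.
#' @param covariates optional data.frame of per-sample covariates
#'   (outcome, subject, time point, ...), row-aligned with `sample`.
#' @return an object of class `experiment_design` (a data.frame plus
#'   attributes).
#' @export
experiment_design <- function(sample, unit = sample,
                              hierarchy = rep("all", length(sample)),
                              active_markers = NULL,
                              starting_population = "root",
                              covariates = NULL) {
  sample <- as.character(sample)
  if (anyDuplicated(sample)) stop("duplicate sample identifiers")
  if (length(unit) != length(sample)) stop("unit must align with sample")
  if (length(hierarchy) != length(sample)) stop("hierarchy must align with sample")
  hmap <- tapply(as.character(hierarchy), as.character(unit), unique)
  if (any(lengths(hmap) > 1))
    stop("every sample of a unit must share one hierarchy label")
  d <- data.frame(sample = sample, unit = as.character(unit),
                  hierarchy = as.character(hierarchy),
                  stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(sample))
    d <- cbind(d, covariates)
  }
  structure(d, class = c("experiment_design", "data.frame"),
            active_markers = active_markers,
            starting_population = starting_population)
}

#' Concatenate samples belonging to one experimental unit
#' @param samples list of [expression_matrix] objects sharing a unit.
#' @return an [expression_matrix] for the unit, with per-cell sample origin in
#'   attribute `"sample_origin"`.
#' @export
concatenate_unit <- function(samples) {
  stopifnot(length(samples) >= 1)
  unit <- unique(vapply(samples, function(s) s$unit_id, ""))
  if (length(unit) != 1) stop("samples belong to different units")
  mk <- samples[[1]]$markers
  for (s in samples) if (!identical(s$markers, mk))
    stop(sprintf("sample '%s': marker panel differs within unit '%s'",
                 s$sample_id, unit))
  vals <- do.call(rbind, lapply(samples, function(s) s$values))
  em <- expression_matrix(vals, mk, sample_id = unit, unit_id = unit)
  attr(em, "sample_origin") <- rep(vapply(samples, function(s) s$sample_id, ""),
                                   vapply(samples, function(s) nrow(s$values), 0L))
  em
}
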
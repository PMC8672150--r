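#' Minimal FCS 3.0/3.1 reader
#'
#' Reads the TEXT segment and the DATA segment of a single-dataset FCS file.
#' Supported data types: `F` (32-bit float), `D` (64-bit double), and `I`
#' (unsigned integers of 8/16/32/64 bits per `$PnB`). List mode only
#' (`$MODE L`). No compensation or transformation is applied. Column names
#' follow the stain keyword `$PnS` when present and non-empty, otherwise the
#' detector name `$PnN`; a resulting name collision is an error.
#'
#' @param path path to an FCS file.
#' @return list with `values` (event matrix) and `keywords` (named character).
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 58))
  version <- substr(hdr, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("unsupported FCS version: ", version)
  off <- function(a, b) {
    v <- suppressWarnings(as.numeric(trimws(substr(hdr, a, b))))
    if (is.na(v)) stop("malformed FCS header")
    v
  }
  text_beg <- off(11, 18); text_end <- off(19, 26)
  data_beg <- off(27, 34); data_end <- off(35, 42)

  seek(con, text_beg)
  txt <- rawToChar(readBin(con, "raw", text_end - text_beg + 1))
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- setNames(trimws(parts[seq(2, length(parts), 2)]),
                 toupper(trimws(parts[seq(1, length(parts), 2)])))
  getkw <- function(key) if (key %in% names(kw)) kw[[key]] else NULL

  npar <- as.integer(getkw("$PAR"))
  ntot <- as.integer(getkw("$TOT"))
  dtype <- toupper(getkw("$DATATYPE"))
  endian <- getkw("$BYTEORD")
  endian <- if (identical(endian, "4,3,2,1")) "big" else "little"
  if (!is.null(getkw("$MODE")) && toupper(getkw("$MODE")) != "L")
    stop("only list-mode FCS data are supported")
  if (data_beg == 0 && !is.null(getkw("$BEGINDATA"))) {
    data_beg <- as.numeric(getkw("$BEGINDATA"))
    data_end <- as.numeric(getkw("$ENDDATA"))
  }

  seek(con, data_beg)
  nval <- npar * ntot
  values <- switch(dtype,
    F = readBin(con, "numeric", nval, size = 4, endian = endian),
    D = readBin(con, "numeric", nval, size = 8, endian = endian),
    I = {
      bits <- as.integer(getkw(sprintf("$P%dB", 1)))
      bset <- vapply(seq_len(npar),
                     function(i) as.integer(getkw(sprintf("$P%dB", i))), 0L)
      if (length(unique(bset)) != 1)
        stop("mixed $PnB widths for integer data are not supported")
      sz <- bits / 8
      if (!sz %in% c(1, 2, 4, 8)) stop("unsupported $PnB: ", bits)
      v <- readBin(con, "integer", nval, size = min(sz, 4), endian = endian,
                   signed = sz >= 4)
      if (sz <= 2) v[v < 0] <- v[v < 0] + 2^(8 * sz)
      as.numeric(v)
    },
    stop("unsupported $DATATYPE: ", dtype))
  if (length(values) < nval)
    stop("FCS data segment truncated: expected ", nval, " values")
  m <- matrix(values, nrow = ntot, ncol = npar, byrow = TRUE)

  nm <- vapply(seq_len(npar), function(i) {
    s <- getkw(sprintf("$P%dS", i))
    n <- getkw(sprintf("$P%dN", i))
    if (!is.null(s) && nzchar(s)) s else if (!is.null(n)) n else sprintf("P%d", i)
  }, "")
  if (anyDuplicated(nm))
    stop("FCS parameter name collision after $PnS/$PnN resolution: ",
         paste(nm[duplicated(nm)], collapse = ", "))
  colnames(m) <- nm
  list(values = m, keywords = kw)
}
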
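# Spectral dataset container and delimited-text I/O.
#
# On-disk format: CSV, "." decimal, one header row. First column "sample_id",
# then one column per wavelength (header = wavelength in nm), then optional
# indicator columns with the reserved names "SSC", "MC", "VC".

RESERVED_INDICATORS <- c("SSC", "MC", "VC")

#' Construct a spectral dataset
#'
#' Bundles a strictly increasing wavelength axis (nm), an N x P reflectance
#' matrix and optional per-sample indicator values into a validated container.
#'
#' @param wavelengths_nm numeric vector of wavelengths in nm, strictly
#'   increasing, length P.
#' @param reflectance numeric N x P matrix of reflectance values
#'   (dimensionless; values outside `[0, 1]` are kept, see Details).
#' @param sample_ids character vector of N sample labels. Defaults to
#'   `"S1" ... "SN"`.
#' @param indicators optional named list mapping an indicator name (one of
#'   `"SSC"`, `"MC"`, `"VC"`) to a numeric N-vector.
#'
#' @details Negative reflectance (sample signal below the dark reference) is
#'   retained rather than clipped — silent clipping would hide acquisition
#'   faults — but is counted in the `load_report` attribute so callers can
#'   inspect it.
#'
#' @return An object of class `"spectral_dataset"`: a list with elements
#'   `wavelengths_nm`, `reflectance`, `sample_ids`, `indicators`.
#' @export
spectral_dataset <- function(wavelengths_nm, reflectance,
                             sample_ids = NULL, indicators = NULL) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  reflectance <- as.matrix(reflectance)
  storage.mode(reflectance) <- "double"
  if (length(wavelengths_nm) != ncol(reflectance))
    stop("wavelength axis length (", length(wavelengths_nm),
         ") does not match number of spectral columns (", ncol(reflectance), ")")
  if (length(wavelengths_nm) >= 2 && any(diff(wavelengths_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(!is.finite(wavelengths_nm)))
    stop("non-finite wavelength values")
  if (length(reflectance) && any(!is.finite(reflectance)))
    stop("non-finite reflectance values")
  n <- nrow(reflectance)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n)
    stop("sample_ids length (", length(sample_ids),
         ") does not match number of rows (", n, ")")
  if (!is.null(indicators)) {
    if (is.null(names(indicators)) || !all(names(indicators) %in% RESERVED_INDICATORS))
      stop("indicator names must be among: ",
           paste(RESERVED_INDICATORS, collapse = ", "))
    for (nm in names(indicators)) {
      indicators[[nm]] <- as.numeric(indicators[[nm]])
      if (length(indicators[[nm]]) != n)
        stop("indicator '", nm, "' has length ", length(indicators[[nm]]),
             ", expected ", n)
      if (any(!is.finite(indicators[[nm]])))
        stop("non-finite values in indicator '", nm, "'")
    }
  }
  dimnames(reflectance) <- NULL
  rownames(reflectance) <- sample_ids
  out <- structure(
    list(wavelengths_nm = wavelengths_nm, reflectance = reflectance,
         sample_ids = sample_ids, indicators = indicators),
    class = "spectral_dataset")
  attr(out, "load_report") <- list(
    n_negative = sum(reflectance < 0),
    n_above_one = sum(reflectance > 1))
  out
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat("<spectral_dataset>\n")
  cat(sprintf("  %d samples x %d wavelengths (%.4g - %.4g nm)\n",
              nrow(x$reflectance), length(x$wavelengths_nm),
              min(x$wavelengths_nm), max(x$wavelengths_nm)))
  if (!is.null(x$indicators))
    cat("  indicators:", paste(names(x$indicators), collapse = ", "), "\n")
  rep <- attr(x, "load_report")
  if (!is.null(rep) && rep$n_negative > 0)
    cat("  note:", rep$n_negative, "negative reflectance values retained\n")
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$reflectance)

#' Subset the samples of a spectral dataset
#'
#' @param x a [spectral_dataset()].
#' @param i sample (row) index vector.
#' @param ... unused.
#' @return a `spectral_dataset` with the selected samples.
#' @export
`[.spectral_dataset` <- function(x, i, ...) {
  ind <- x$indicators
  if (!is.null(ind)) ind <- lapply(ind, function(v) v[i])
  spectral_dataset(x$wavelengths_nm, x$reflectance[i, , drop = FALSE],
                   x$sample_ids[i], ind)
}

# number format used on disk; %.10g round-trips through re-write identically
.spec_fmt <- "%.10g"

#' Read a spectral matrix from delimited text
#'
#' Parses the package's CSV layout: header row of wavelengths (nm), one row
#' per sample starting with the sample id, optional trailing indicator columns
#' named `"SSC"`, `"MC"`, `"VC"`.
#'
#' @param path path to the CSV file.
#' @param sep field separator (default `","`; the decimal mark is always
#'   `"."`).
#' @return a [spectral_dataset()]; column order of the file is preserved.
#' @export
read_spectra_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- count.fields(path, sep = sep, quote = "\"")
  if (length(unique(nf)) > 1)
    stop("format error in '", path, "': ragged rows (fields per row: ",
         paste(unique(nf), collapse = ", "), ")")
  raw <- read.csv(path, sep = sep, check.names = FALSE,
                  colClasses = "character", header = TRUE)
  if (names(raw)[1] != "sample_id")
    stop("format error: first column must be 'sample_id', found '",
         names(raw)[1], "'")
  cols <- names(raw)[-1]
  is_ind <- cols %in% RESERVED_INDICATORS
  wl_cols <- cols[!is_ind]
  wl <- suppressWarnings(as.numeric(wl_cols))
  if (any(is.na(wl)))
    stop("format error: non-numeric wavelength header(s): ",
         paste(head(wl_cols[is.na(wl)], 3), collapse = ", "))
  if (length(wl) >= 2 && any(diff(wl) <= 0))
    stop("validation error: wavelength header not strictly increasing")
  parse_col <- function(v, colname) {
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) | !is.finite(out))
    if (length(bad))
      stop("parse error: non-numeric or non-finite value '", v[bad[1]],
           "' at row ", bad[1], ", column '", colname, "'")
    out
  }
  n <- nrow(raw)
  refl <- matrix(0, n, length(wl_cols))
  for (j in seq_along(wl_cols))
    refl[, j] <- parse_col(raw[[wl_cols[j]]], wl_cols[j])
  indicators <- NULL
  if (any(is_ind)) {
    indicators <- list()
    for (nm in cols[is_ind]) indicators[[nm]] <- parse_col(raw[[nm]], nm)
  }
  spectral_dataset(wl, refl, raw$sample_id, indicators)
}

#' Write a spectral dataset to delimited text
#'
#' Inverse of [read_spectra_table()]: values are written with 10 significant
#' digits, so write -> read -> write is byte-identical and read(write(x))
#' reproduces `x` to that precision. Indicator columns, when present, follow
#' the spectral columns.
#'
#' @param dataset a [spectral_dataset()].
#' @param path output file path.
#' @param sep field separator (default `","`).
#' @return invisibly, `path`.
#' @export
write_spectra_table <- function(dataset, path, sep = ",") {
  stopifnot(inherits(dataset, "spectral_dataset"))
  wl_hdr <- sprintf(.spec_fmt, dataset$wavelengths_nm)
  hdr <- c("sample_id", wl_hdr, names(dataset$indicators))
  n <- nrow(dataset$reflectance)
  rows <- character(n)
  for (i in seq_len(n)) {
    cells <- c(dataset$sample_ids[i],
               sprintf(.spec_fmt, dataset$reflectance[i, ]))
    if (!is.null(dataset$indicators))
      cells <- c(cells, vapply(dataset$indicators,
                               function(v) sprintf(.spec_fmt, v[i]), ""))
    rows[i] <- paste(cells, collapse = sep)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(hdr, collapse = sep), rows), con)
  invisible(path)
}

#' Convert raw instrument counts to diffuse reflectance
#'
#' Standard dark/white calibration: with `S` the sample counts, `D` the dark
#' spectrum (light source off) and `W` the white-reference spectrum,
#' reflectance is `R = (S - D) / (W - D)`, channel by channel. The result is
#' invariant to a common additive offset and to a common rescaling of all
#' three count vectors.
#'
#' @param sample_counts,dark_counts,reference_counts numeric vectors of equal
#'   length P (instrument counts, arbitrary units).
#' @return numeric P-vector of reflectance.
#' @export
counts_to_reflectance <- function(sample_counts, dark_counts, reference_counts) {
  sample_counts <- as.numeric(sample_counts)
  dark_counts <- as.numeric(dark_counts)
  reference_counts <- as.numeric(reference_counts)
  p <- length(sample_counts)
  if (length(dark_counts) != p || length(reference_counts) != p)
    stop("count vectors must have equal length")
  denom <- reference_counts - dark_counts
  zero <- which(denom == 0)
  if (length(zero))
    stop("calibration error: reference equals dark at channel(s) ",
         paste(head(zero, 10), collapse = ", "))
  (sample_counts - dark_counts) / denom
}
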
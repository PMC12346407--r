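#' Construct an absorbance spectrum
#'
#' A spectrum is a data frame with columns `wavelength_nm` and `absorbance`
#' on a strictly increasing, uniformly spaced wavelength grid. All derivative
#' and area computations in the package assume grid uniformity, so it is
#' enforced here (within 1e-9 nm).
#'
#' @param wavelength_nm Numeric vector of wavelengths in nm, uniform grid.
#' @param absorbance Numeric vector of absorbances (dimensionless), same length.
#' @param kind `"absorbance"` for a raw spectrum or `"derivative"` for a
#'   dA/dlambda curve (units absorbance/nm).
#' @return An object of class `ax_spectrum` (a data frame).
#' @export
ax_spectrum <- function(wavelength_nm, absorbance, kind = c("absorbance", "derivative")) {
  kind <- match.arg(kind)
  wavelength_nm <- as.numeric(wavelength_nm)
  absorbance <- as.numeric(absorbance)
  if (length(wavelength_nm) < 2L) abort_format("a spectrum needs at least 2 points")
  if (length(absorbance) != length(wavelength_nm)) {
    abort_format("`wavelength_nm` and `absorbance` must have the same length")
  }
  if (anyNA(wavelength_nm) || anyNA(absorbance)) abort_format("spectrum contains NA values")
  steps <- diff(wavelength_nm)
  if (any(steps <= 0)) abort_format("wavelength grid must be strictly increasing")
  if (max(steps) - min(steps) > 1e-9) {
    abort_format("wavelength grid must be uniform (spacing varies by more than 1e-9 nm)")
  }
  out <- data.frame(wavelength_nm = wavelength_nm, absorbance = absorbance)
  class(out) <- c("ax_spectrum", "data.frame")
  attr(out, "kind") <- kind
  attr(out, "step_nm") <- steps[1L]
  out
}

#' @export
print.ax_spectrum <- function(x, ...) {
  kind <- attr(x, "kind") %||% "absorbance"
  cat(sprintf(
    "<ax_spectrum: %s, %d points, %.1f-%.1f nm, step %.3g nm>\n",
    kind, nrow(x), min(x$wavelength_nm), max(x$wavelength_nm), attr(x, "step_nm")
  ))
  invisible(x)
}

is_derivative_spectrum <- function(x) {
  inherits(x, "ax_spectrum") && identical(attr(x, "kind"), "derivative")
}

#' Read or write a spectrum CSV
#'
#' CSV layout: header `wavelength_nm,absorbance`, dot decimal separator.
#'
#' @param path File path.
#' @param x An `ax_spectrum`.
#' @return `read_spectrum_csv()` returns an `ax_spectrum`;
#'   `write_spectrum_csv()` returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path) {
  df <- read_csv_checked(path, c("wavelength_nm", "absorbance"))
  ax_spectrum(df$wavelength_nm, df$absorbance)
}

#' @rdname read_spectrum_csv
#' @export
write_spectrum_csv <- function(x, path) {
  stopifnot(inherits(x, "ax_spectrum"))
  utils::write.csv(as.data.frame(x)[c("wavelength_nm", "absorbance")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Shared CSV reader: parse failures and missing columns become classed parse
# errors that name the offending column/row.
read_csv_checked <- function(path, required_cols) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE),
    error = function(e) abort_parse(sprintf("cannot parse CSV '%s': %s", path, conditionMessage(e)))
  )
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    abort_parse(sprintf("CSV '%s' is missing required column(s): %s",
                        path, paste(missing, collapse = ", ")))
  }
  for (col in required_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & nzchar(trimws(as.character(v))))
      if (length(bad)) {
        abort_parse(sprintf("CSV '%s': column '%s' is non-numeric at row %d",
                            path, col, bad[1L]))
      }
      df[[col]] <- vn
    }
    if (anyNA(df[[col]])) {
      abort_parse(sprintf("CSV '%s': column '%s' has a missing value at row %d",
                          path, col, which(is.na(df[[col]]))[1L]))
    }
  }
  df
}
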
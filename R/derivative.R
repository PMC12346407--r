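#' First-derivative spectrum by local polynomial smoothing
#'
#' Computes dA/dlambda with a Savitzky-Golay filter: a polynomial of order
#' `poly_order` is fit by least squares in a sliding window of
#' `smoothing_window` points and differentiated analytically; the end points
#' use the one-sided fits built into the filter matrix. Exact for spectra that
#' are polynomials of degree <= `poly_order`.
#'
#' @param spec An `ax_spectrum` (raw absorbance).
#' @param smoothing_window Odd window length in points (default 11, i.e.
#'   5 nm on the native 0.5 nm grid).
#' @param poly_order Local polynomial order (default 2); the window must
#'   satisfy `smoothing_window >= poly_order + 2`.
#' @return An `ax_spectrum` of kind `"derivative"` on the same grid, in
#'   absorbance/nm.
#' @export
first_derivative <- function(spec, smoothing_window = 11, poly_order = 2) {
  if (!inherits(spec, "ax_spectrum")) abort_format("`spec` must be an ax_spectrum")
  if (is_derivative_spectrum(spec)) abort_domain("`spec` is already a derivative spectrum")
  n <- nrow(spec)
  if (smoothing_window %% 2 != 1) abort_domain("smoothing_window must be odd")
  if (smoothing_window < poly_order + 2) {
    abort_domain("smoothing_window must be at least poly_order + 2")
  }
  if (smoothing_window >= n) abort_domain("smoothing_window must be shorter than the spectrum")
  step <- attr(spec, "step_nm")
  d <- signal::sgolayfilt(spec$absorbance, p = poly_order, n = smoothing_window,
                          m = 1, ts = step)
  ax_spectrum(spec$wavelength_nm, d, kind = "derivative")
}

window_indices <- function(spec, window) {
  wl <- spec$wavelength_nm
  if (window[1] < min(wl) - 1e-9 || window[2] > max(wl) + 1e-9) {
    abort_domain(sprintf("window [%g, %g] nm lies outside the spectral grid", window[1], window[2]))
  }
  which(wl >= window[1] - 1e-9 & wl <= window[2] + 1e-9)
}

#' Windowed derivative peaks and areas under the curve
#'
#' Within the two fixed analysis windows (420-450 nm and 455-480 nm) the
#' derivative peak is the maximum of dA/dlambda, and the AUC is the
#' trapezoidal integral of the configured integrand on the native grid. The
#' default integrand is the first-derivative curve itself; set
#' `auc_integrand = "absorbance"` to integrate the raw spectrum instead (both
#' readings of an area "for each peak" of a derivative spectrum are supported).
#'
#' @param deriv Derivative spectrum (`first_derivative()` output).
#' @param raw The raw absorbance spectrum on the same grid.
#' @param auc_integrand `"derivative"` (default) or `"absorbance"`.
#' @return A `derivative_features` list: `peak1`, `peak2` (absorbance/nm),
#'   `auc1`, `auc2`, `a468` (raw absorbance at 468 nm), window bounds and the
#'   integrand used.
#' @export
extract_features <- function(deriv, raw, auc_integrand = c("derivative", "absorbance")) {
  auc_integrand <- match.arg(auc_integrand)
  if (!is_derivative_spectrum(deriv)) abort_format("`deriv` must be a derivative spectrum")
  if (!inherits(raw, "ax_spectrum")) abort_format("`raw` must be an ax_spectrum")
  if (nrow(deriv) != nrow(raw) ||
      max(abs(deriv$wavelength_nm - raw$wavelength_nm)) > 1e-9) {
    abort_format("`deriv` and `raw` must share the same wavelength grid")
  }
  integrand <- if (auc_integrand == "derivative") deriv$absorbance else raw$absorbance
  feat <- function(window) {
    idx <- window_indices(deriv, window)
    if (length(idx) < 2L) abort_domain("analysis window contains fewer than 2 grid points")
    list(peak = max(deriv$absorbance[idx]),
         auc = pracma::trapz(deriv$wavelength_nm[idx], integrand[idx]))
  }
  f1 <- feat(WINDOW_1)
  f2 <- feat(WINDOW_2)
  a468 <- stats::approx(raw$wavelength_nm, raw$absorbance, xout = 468)$y
  structure(list(peak1 = f1$peak, peak2 = f2$peak,
                 auc1 = f1$auc, auc2 = f2$auc, a468 = a468,
                 window1 = WINDOW_1, window2 = WINDOW_2,
                 auc_integrand = auc_integrand),
            class = "derivative_features")
}

#' @export
print.derivative_features <- function(x, ...) {
  cat(sprintf(
    paste0("<derivative_features (AUC integrand: %s)>\n",
           "  420-450 nm: peak dA/dl = %.5g, AUC = %.5g\n",
           "  455-480 nm: peak dA/dl = %.5g, AUC = %.5g\n",
           "  A(468 nm)  = %.5g\n"),
    x$auc_integrand, x$peak1, x$auc1, x$peak2, x$auc2, x$a468
  ))
  invisible(x)
}

# All feature kinds for one (spectrum, derivative) pair, as a named vector.
feature_vector <- function(spec, smoothing_window = 11, poly_order = 2,
                           auc_integrand = "derivative") {
  d <- first_derivative(spec, smoothing_window, poly_order)
  f <- extract_features(d, spec, auc_integrand)
  c(dA_dl_peak1 = f$peak1, dA_dl_peak2 = f$peak2,
    AUC1 = f$auc1, AUC2 = f$auc2, A468 = f$a468)
}
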
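#' Calibration curve from concentration-feature pairs
#'
#' Ordinary least-squares line `feature = slope * concentration + intercept`.
#' The fit is not forced through the origin: real extract calibrations show
#' small non-zero intercepts. Two points are accepted but flagged as
#' under-determined (R-squared is 1 by construction and no inference is
#' possible); fewer than two distinct concentrations is a singularity.
#'
#' @param concentrations Analyte concentrations, mg/g.
#' @param features Feature values (derivative peak, AUC, or raw absorbance).
#' @param feature_kind Label, e.g. `"AUC1"` or `"dA_dl_peak1"`.
#' @param window_label Text label for the wavelength window.
#' @param day Storage day the calibration belongs to.
#' @return A `calibration_curve` with `slope`, `intercept`, `r_squared`,
#'   `n`, and `under_determined`.
#' @export
calibrate <- function(concentrations, features, feature_kind = "AUC1",
                      window_label = "", day = NA_real_) {
  if (length(concentrations) != length(features)) {
    abort_domain("`concentrations` and `features` must have equal length")
  }
  n <- length(concentrations)
  if (n < 2L) abort_domain("calibration needs at least 2 (concentration, feature) pairs")
  if (length(unique(concentrations)) < 2L) {
    abort_singular("calibration concentrations are all equal; slope is not identifiable")
  }
  under <- n < 3L
  if (under) {
    warning("calibration on only 2 points is under-determined for inference",
            call. = FALSE)
  }
  fit <- stats::lm(features ~ concentrations)
  sst <- sum((features - mean(features))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = r2, n = n,
    feature_kind = feature_kind, window_label = window_label, day = day,
    under_determined = under
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve %s%s>\n  feature = %.4f x [AX] + %.4f   (R2 = %.4f, n = %d%s)\n",
              x$feature_kind,
              if (is.finite(x$day)) sprintf(", day %g", x$day) else "",
              x$slope, x$intercept, x$r_squared, x$n,
              if (x$under_determined) ", under-determined" else ""))
  invisible(x)
}

#' Invert a calibration curve
#'
#' @param feature_value Measured feature value(s).
#' @param curve A `calibration_curve`.
#' @return Estimated concentration(s), mg/g: `(feature - intercept) / slope`.
#'   Negative estimates are returned as-is with a warning and a
#'   `negative` attribute flag.
#' @export
estimate_concentration <- function(feature_value, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) abort_singular("calibration slope is zero; cannot invert")
  est <- (feature_value - curve$intercept) / curve$slope
  neg <- est < 0
  if (any(neg)) {
    warning(sprintf("%d concentration estimate(s) below zero; check the calibration range",
                    sum(neg)), call. = FALSE)
    attr(est, "negative") <- neg
  }
  est
}

#' First-order degradation fit
#'
#' Fits `ln c(t) = ln c0 - k t` by least squares on the log scale, the
#' standard model for carotenoid loss during storage.
#'
#' @param times Time points, days (>= 2 distinct).
#' @param concentrations Concentrations, mg/g, all positive.
#' @return A `decay_fit` with rate constant `k` (per day), initial
#'   concentration `c0` (mg/g) and `r_squared`.
#' @export
fit_first_order_decay <- function(times, concentrations) {
  if (length(times) != length(concentrations)) {
    abort_domain("`times` and `concentrations` must have equal length")
  }
  if (length(times) < 2L) abort_domain("need at least 2 time points")
  if (any(concentrations <= 0)) {
    abort_domain("first-order decay requires positive concentrations")
  }
  if (length(unique(times)) < 2L) abort_singular("all time points are equal")
  fit <- stats::lm(log(concentrations) ~ times)
  lg <- log(concentrations)
  sst <- sum((lg - mean(lg))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(list(
    k = -unname(stats::coef(fit)[2L]),
    c0 = exp(unname(stats::coef(fit)[1L])),
    r_squared = r2, n = length(times)
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> c(t) = %.4g * exp(-%.4g * t)   (R2 = %.4f, n = %d)\n",
              x$c0, x$k, x$r_squared, x$n))
  invisible(x)
}

#' Percent retention of the analyte
#'
#' @param c_t Concentration at time t, mg/g.
#' @param c_0 Initial concentration, mg/g (> 0).
#' @return `100 * c_t / c_0` (percent).
#' @export
retention_percent <- function(c_t, c_0) {
  if (any(c_0 <= 0)) abort_domain("`c_0` must be positive")
  100 * c_t / c_0
}

#' Calibration panel across storage days and feature kinds
#'
#' Builds the full calibration table of a storage study: for each day, spectra
#' at the given concentrations are reduced to derivative peaks, AUCs and raw
#' absorbance at 468 nm, and each feature kind is regressed on concentration.
#'
#' @param spectra_by_day Nested list: `spectra_by_day[[d]][[i]]` is the
#'   `ax_spectrum` for `days[d]`, `concentrations[i]`.
#' @param concentrations Concentration series, mg/g.
#' @param days Storage days.
#' @param smoothing_window,poly_order Passed to [first_derivative()].
#' @param auc_integrand Passed to [extract_features()].
#' @return Data frame with columns `feature_kind`, `day`, `slope`,
#'   `intercept`, `r_squared`.
#' @export
calibration_table <- function(spectra_by_day, concentrations, days,
                              smoothing_window = 11, poly_order = 2,
                              auc_integrand = "derivative") {
  if (length(spectra_by_day) != length(days)) {
    abort_domain("`spectra_by_day` must have one element per day")
  }
  rows <- list()
  for (d in seq_along(days)) {
    specs <- spectra_by_day[[d]]
    if (length(specs) != length(concentrations)) {
      abort_domain("each day needs one spectrum per concentration")
    }
    fmat <- vapply(specs, feature_vector, numeric(5),
                   smoothing_window = smoothing_window, poly_order = poly_order,
                   auc_integrand = auc_integrand)
    for (kind in rownames(fmat)) {
      cc <- calibrate(concentrations, fmat[kind, ], feature_kind = kind, day = days[d])
      rows[[length(rows) + 1L]] <- data.frame(
        feature_kind = kind, day = days[d], slope = cc$slope,
        intercept = cc$intercept, r_squared = cc$r_squared
      )
    }
  }
  do.call(rbind, rows)
}
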
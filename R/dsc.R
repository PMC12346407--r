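#' Construct a DSC curve
#'
#' Heat flow versus temperature at one linear heating rate. Temperatures stay
#' in degrees Celsius at the interface; kelvin conversion happens internally
#' wherever 1/T enters a computation.
#'
#' @param temperature_C Strictly increasing temperatures, degC (>= 50 points).
#' @param heat_flow Heat-flow signal, instrument units, same length.
#' @param heating_rate Heating rate in K/min (> 0).
#' @return A `dsc_curve` (a data frame with attribute `heating_rate`).
#' @export
dsc_curve <- function(temperature_C, heat_flow, heating_rate) {
  temperature_C <- as.numeric(temperature_C)
  heat_flow <- as.numeric(heat_flow)
  if (length(temperature_C) < 50L) abort_format("a DSC curve needs at least 50 points")
  if (length(heat_flow) != length(temperature_C)) {
    abort_format("`temperature_C` and `heat_flow` must have the same length")
  }
  if (any(diff(temperature_C) <= 0)) abort_format("temperatures must be strictly increasing")
  if (!is.numeric(heating_rate) || length(heating_rate) != 1L || heating_rate <= 0) {
    abort_domain("`heating_rate` must be a single positive number (K/min)")
  }
  out <- data.frame(temperature_C = temperature_C, heat_flow = heat_flow)
  class(out) <- c("dsc_curve", "data.frame")
  attr(out, "heating_rate") <- heating_rate
  out
}

#' @export
print.dsc_curve <- function(x, ...) {
  cat(sprintf("<dsc_curve: %d points, %.1f-%.1f degC, beta = %g K/min>\n",
              nrow(x), min(x$temperature_C), max(x$temperature_C),
              attr(x, "heating_rate")))
  invisible(x)
}

#' Read or write DSC curve CSVs
#'
#' CSV layout: `temperature_C,heat_flow,heating_rate_K_min` (the rate column
#' is constant within one curve).
#'
#' @param path File path.
#' @param x A `dsc_curve`.
#' @return `read_dsc_csv()` returns a `dsc_curve`.
#' @export
read_dsc_csv <- function(path) {
  df <- read_csv_checked(path, c("temperature_C", "heat_flow", "heating_rate_K_min"))
  rate <- unique(df$heating_rate_K_min)
  if (length(rate) != 1L) abort_parse(sprintf("CSV '%s': heating_rate_K_min is not constant", path))
  dsc_curve(df$temperature_C, df$heat_flow, rate)
}

#' @rdname read_dsc_csv
#' @export
write_dsc_csv <- function(x, path) {
  stopifnot(inherits(x, "dsc_curve"))
  df <- data.frame(temperature_C = x$temperature_C, heat_flow = x$heat_flow,
                   heating_rate_K_min = attr(x, "heating_rate"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

default_baseline_region <- function(curve) {
  lo <- min(curve$temperature_C)
  c(lo, lo + 0.30 * (max(curve$temperature_C) - lo))
}

#' Fit the pre-transition instrument baseline
#'
#' Least-squares line through the heat flow over a region below the exotherm.
#'
#' @param curve A `dsc_curve`.
#' @param fit_region Length-2 degC interval; defaults to the lower 30\% of the
#'   temperature range (the region must stay clear of the exotherm's leading
#'   tail, or the fitted baseline absorbs early reaction heat and biases both
#'   the onset and the conversion curve).
#' @return A `dsc_baseline` with `intercept`, `slope` (per degC), residual
#'   `sd` and the region used.
#' @export
fit_baseline <- function(curve, fit_region = NULL) {
  stopifnot(inherits(curve, "dsc_curve"))
  fit_region <- fit_region %||% default_baseline_region(curve)
  if (fit_region[1] < min(curve$temperature_C) - 1e-9 ||
      fit_region[2] > max(curve$temperature_C) + 1e-9) {
    abort_domain("baseline fit_region lies outside the curve's temperature range")
  }
  idx <- which(curve$temperature_C >= fit_region[1] & curve$temperature_C <= fit_region[2])
  if (length(idx) < 10L) abort_domain("baseline region must contain at least 10 points")
  fit <- stats::lm(curve$heat_flow[idx] ~ curve$temperature_C[idx])
  structure(list(
    intercept = unname(stats::coef(fit)[1L]),
    slope = unname(stats::coef(fit)[2L]),
    sd = stats::sd(stats::residuals(fit)),
    region = fit_region
  ), class = "dsc_baseline")
}

baseline_at <- function(baseline, temperature_C) {
  baseline$intercept + baseline$slope * temperature_C
}

#' Detect the oxidation onset temperature
#'
#' Two constructions of the onset To are offered. `"tangent"` (default, the
#' standard thermal-analysis construction): the extrapolated baseline is
#' intersected with the tangent drawn at the point of maximum rising slope on
#' the leading edge of the exotherm. `"threshold"`: the first temperature at
#' which the baseline-subtracted signal exceeds `k` times the baseline
#' residual SD -- a direct reading of "significant deviation from the
#' baseline".
#'
#' @param curve A `dsc_curve`.
#' @param method `"tangent"` or `"threshold"`.
#' @param baseline A `dsc_baseline`, or `NULL` to fit one on the default
#'   region.
#' @param k Threshold multiplier (default 10 residual SDs). Also used as the
#'   detectability guard for both methods.
#' @param min_deviation Absolute floor for the detectability guard (useful for
#'   noise-free synthetic curves where the residual SD is ~0).
#' @param smooth_window Odd Savitzky-Golay window (points) applied to the
#'   signal before the tangent/threshold construction, so the steepest-slope
#'   point is not chosen by point-to-point noise; default 51; 0 disables.
#' @param slope_window Window (points) for the local-polynomial slope estimate
#'   in the tangent construction; derivative estimation needs wider support
#'   than smoothing, so the default is `4 * smooth_window + 1`. Ignored (raw
#'   segment slopes are used) when smoothing is disabled or the temperature
#'   grid is non-uniform.
#' @return An `onset_result` with `To` (degC), `method` and
#'   `baseline_coefficients`.
#' @export
detect_onset <- function(curve, method = c("tangent", "threshold"),
                         baseline = NULL, k = 10, min_deviation = 0,
                         smooth_window = 51, slope_window = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "dsc_curve"))
  baseline <- baseline %||% fit_baseline(curve)
  hf <- smooth_signal(curve$heat_flow, smooth_window)
  dev <- hf - baseline_at(baseline, curve$temperature_C)
  guard <- max(k * baseline$sd, min_deviation, .Machine$double.eps)
  i_peak <- which.max(dev)
  if (!is.finite(dev[i_peak]) || dev[i_peak] <= guard) {
    abort_domain("no onset detected: heat flow never deviates significantly from the baseline")
  }
  after <- curve$temperature_C > baseline$region[2]

  To <- if (method == "threshold") {
    i <- which(dev > guard & after & seq_along(dev) <= i_peak)
    if (!length(i)) abort_domain("no onset detected above the threshold")
    curve$temperature_C[i[1L]]
  } else {
    # Leading edge: from where the signal first clears 5% of the peak
    # deviation up to the peak itself.
    start_lvl <- 0.05 * dev[i_peak]
    i0 <- which(dev >= start_lvl & after & seq_along(dev) <= i_peak)
    if (!length(i0)) abort_domain("no onset detected: exotherm leading edge not found")
    idx <- i0[1L]:i_peak
    if (length(idx) < 2L) abort_domain("no onset detected: exotherm leading edge too short")
    tC <- curve$temperature_C
    steps <- diff(tC)
    uniform <- (max(steps) - min(steps)) < 1e-9
    if (!is.null(smooth_window) && smooth_window >= 5L && uniform) {
      sw <- as.integer(slope_window %||% (4L * as.integer(smooth_window) + 1L))
      if (sw %% 2L == 0L) sw <- sw + 1L
      if (sw >= nrow(curve)) sw <- nrow(curve) - 1L - (nrow(curve) %% 2L)
      sl <- signal::sgolayfilt(curve$heat_flow, p = 2, n = sw, m = 1, ts = steps[1L])
      j <- idx[which.max(sl[idx])]
      Tm <- tC[j]; ym <- hf[j]; sm <- sl[j]
    } else {
      slopes <- diff(hf[idx]) / diff(tC[idx])
      j <- which.max(slopes)
      # Tangent point: midpoint of the steepest segment, slope of that segment.
      Tm <- (tC[idx[j]] + tC[idx[j + 1L]]) / 2
      ym <- (hf[idx[j]] + hf[idx[j + 1L]]) / 2
      sm <- slopes[j]
    }
    if (abs(sm - baseline$slope) < 1e-12) {
      abort_domain("no onset detected: tangent is parallel to the baseline")
    }
    (ym - sm * Tm - baseline$intercept) / (baseline$slope - sm)
  }
  if (To < min(curve$temperature_C) || To > max(curve$temperature_C)) {
    abort_domain("onset construction fell outside the curve's temperature range")
  }
  structure(list(To = To, method = method,
                 baseline_coefficients = c(intercept = baseline$intercept,
                                           slope = baseline$slope)),
            class = "onset_result")
}

#' @export
print.onset_result <- function(x, ...) {
  cat(sprintf("<onset_result> To = %.2f degC (%s method)\n", x$To, x$method))
  invisible(x)
}

# Two-pass baseline for partial-area integration: a first fit on the default
# low-temperature region locates the exotherm, then the baseline is refit on
# everything safely below its leading edge. This keeps the long lever arm of
# the extrapolated baseline short (noise) while excluding the exponential
# leading tail of the reaction (bias).
refine_exotherm_baseline <- function(curve, smooth_window = 51, margin_C = 20) {
  bl <- fit_baseline(curve)
  dev <- curve$heat_flow - baseline_at(bl, curve$temperature_C)
  devs <- smooth_signal(dev, smooth_window)
  # leading edge: noise floor (5 residual SDs) or 0.2% of the peak deviation
  thr <- max(5 * bl$sd, 0.002 * max(devs))
  i1 <- which(devs > thr & curve$temperature_C > bl$region[2L])
  if (length(i1)) {
    lo <- min(curve$temperature_C)
    t_end <- curve$temperature_C[i1[1L]] - margin_C
    if (t_end > lo + 20) bl <- fit_baseline(curve, c(lo, t_end))
  }
  bl
}

smooth_signal <- function(x, window) {
  if (is.null(window) || window < 5L) return(x)
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window - 1L
  if (window >= length(x)) {
    window <- length(x) - 1L - (length(x) %% 2L)
    if (window < 5L) return(x)
  }
  signal::sgolayfilt(x, p = 2, n = window)
}

#' Conversion curve by partial areas
#'
#' The extent of reaction alpha(T) is the cumulative baseline-subtracted
#' exotherm area divided by the total area (trapezoids on the native grid),
#' clipped to [0, 1] and made non-decreasing. This is the standard partial-area
#' construction that lets a fixed conversion level be located on each
#' heating-rate curve for isoconversional analysis.
#'
#' When no baseline is supplied, a two-pass fit is used: the default
#' low-temperature baseline locates the exotherm and the line is then refit on
#' everything below its leading edge, which keeps the extrapolation lever arm
#' short without absorbing early reaction heat. The baseline-subtracted signal
#' is lightly smoothed (Savitzky-Golay) before integration so that rectified
#' noise does not accumulate as spurious area; set `smooth_window = 0` for
#' raw integration.
#'
#' @param curve A `dsc_curve`.
#' @param baseline A `dsc_baseline`, or `NULL` for the refined two-pass fit.
#' @param smooth_window Odd Savitzky-Golay window (points) applied to the
#'   baseline-subtracted signal; default 51 (5 K on a 0.1 K grid); 0 disables.
#' @return A data frame `temperature_C`, `alpha`.
#' @export
conversion_curve <- function(curve, baseline = NULL, smooth_window = 51) {
  stopifnot(inherits(curve, "dsc_curve"))
  baseline <- baseline %||% refine_exotherm_baseline(curve, smooth_window)
  dev <- curve$heat_flow - baseline_at(baseline, curve$temperature_C)
  dev <- pmax(0, smooth_signal(dev, smooth_window))
  if (max(dev) <= 1e-10 * max(1, max(abs(curve$heat_flow)))) {
    abort_domain("non-positive total exotherm area; no conversion curve")
  }
  tC <- curve$temperature_C
  seg <- diff(tC) * (dev[-1L] + dev[-length(dev)]) / 2
  total <- sum(seg)
  if (total <= 0) abort_domain("non-positive total exotherm area; no conversion curve")
  alpha <- c(0, cumsum(seg)) / total
  alpha <- pmin(1, pmax(0, cummax(alpha)))
  data.frame(temperature_C = tC, alpha = alpha)
}

# Temperature (degC) at which alpha(T) crosses `level`, by linear
# interpolation of the conversion curve.
temperature_at_alpha <- function(conv, level) {
  if (level <= 0 || level >= 1) abort_domain("conversion level must lie in (0, 1)")
  i <- which(conv$alpha >= level)
  if (!length(i)) abort_domain(sprintf("conversion never reaches alpha = %g", level))
  i <- i[1L]
  if (i == 1L) return(conv$temperature_C[1L])
  a0 <- conv$alpha[i - 1L]; a1 <- conv$alpha[i]
  t0 <- conv$temperature_C[i - 1L]; t1 <- conv$temperature_C[i]
  if (a1 == a0) return(t1)
  t0 + (level - a0) / (a1 - a0) * (t1 - t0)
}
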
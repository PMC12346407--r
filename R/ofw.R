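#' Ozawa-Flynn-Wall regression
#'
#' Fits the base-10 isoconversional line `log10(beta) = a * (1/T) + b` over
#' the (heating rate, temperature) pairs collected at one fixed conversion
#' level, then inverts the Doyle approximation:
#' activation energy `Ea = -a * R / 0.4567` and pre-exponential factor
#' `A = (R / Ea) * 10^(b + 2.315)` (A in 1/min when beta is in K/min).
#'
#' @param heating_rates Heating rates beta, K/min (>= 3, positive).
#' @param temperatures_K Absolute temperatures at the fixed conversion, kelvin,
#'   all distinct.
#' @return An `ofw_fit` with `slope_a` (K), `intercept_b`, `Ea` (kJ/mol),
#'   `A_pre` (1/min), `r_squared`, and the constants used (`R_gas`,
#'   `doyle_c1`, `doyle_c2`).
#' @export
ofw_fit <- function(heating_rates, temperatures_K) {
  if (length(heating_rates) != length(temperatures_K)) {
    abort_domain("`heating_rates` and `temperatures_K` must have equal length")
  }
  if (length(heating_rates) < 3L) abort_domain("OFW regression needs at least 3 points")
  if (any(heating_rates <= 0)) abort_domain("heating rates must be positive")
  if (any(temperatures_K <= 0)) abort_domain("temperatures must be positive kelvin")
  if (anyDuplicated(temperatures_K)) {
    abort_singular("duplicate temperatures: the OFW regression is singular")
  }
  x <- 1 / temperatures_K
  y <- log10(heating_rates)
  fit <- stats::lm(y ~ x)
  a <- unname(stats::coef(fit)[2L])
  b <- unname(stats::coef(fit)[1L])
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  Ea_J <- -a * GAS_CONSTANT / DOYLE_C2
  A_pre <- if (Ea_J > 0) (GAS_CONSTANT / Ea_J) * 10^(b + DOYLE_C1) else NA_real_
  structure(list(
    slope_a = a, intercept_b = b,
    Ea = Ea_J / 1000, A_pre = A_pre, r_squared = r2,
    n = length(heating_rates),
    R_gas = GAS_CONSTANT, doyle_c1 = DOYLE_C1, doyle_c2 = DOYLE_C2
  ), class = "ofw_fit")
}

#' @export
print.ofw_fit <- function(x, ...) {
  cat(sprintf(
    "<ofw_fit> log10(beta) = %.1f * (1/T) + %.3f   (R2 = %.4f, n = %d)\n  Ea = %.2f kJ/mol,  A = %.4g /min\n",
    x$slope_a, x$intercept_b, x$r_squared, x$n, x$Ea, x$A_pre
  ))
  invisible(x)
}

#' Isoconversional activation-energy profile from a DSC curve set
#'
#' For each requested conversion level alpha, locates the temperature at which
#' each heating-rate curve reaches that conversion (partial-area construction)
#' and runs the Ozawa-Flynn-Wall regression across the set. `alphas = "onset"`
#' uses the detected onset temperature of each curve instead of an
#' isoconversional temperature.
#'
#' @param curves List of `dsc_curve` objects at distinct heating rates.
#' @param alphas Numeric conversion levels in (0, 1), or the string
#'   `"onset"`.
#' @param baseline_region Optional degC interval passed to [fit_baseline()]
#'   for every curve.
#' @param onset_method Passed to [detect_onset()] when `alphas = "onset"`.
#' @return A data frame with one row per conversion level: `alpha`,
#'   `slope_a`, `intercept_b`, `Ea_kJ_mol`, `A_pre_min`, `r_squared`; the
#'   list of `ofw_fit` objects is attached as attribute `fits`.
#' @export
ea_profile <- function(curves, alphas = 0.05, baseline_region = NULL,
                       onset_method = "tangent") {
  if (length(curves) < 3L) abort_domain("need at least 3 heating-rate curves")
  rates <- vapply(curves, function(cv) attr(cv, "heating_rate"), numeric(1))
  # explicit region: honor it; otherwise the refined two-pass baseline
  baselines <- if (is.null(baseline_region)) {
    vector("list", length(curves))
  } else {
    lapply(curves, fit_baseline, fit_region = baseline_region)
  }

  use_onset <- identical(alphas, "onset")
  if (!use_onset && (!is.numeric(alphas) || any(alphas <= 0) || any(alphas >= 1))) {
    abort_domain("conversion levels must lie strictly inside (0, 1)")
  }

  if (use_onset) {
    T_C <- mapply(function(cv, bl) detect_onset(cv, onset_method, bl)$To,
                  curves, baselines)
    fits <- list(ofw_fit(rates, T_C + 273.15))
    lab <- "onset"
  } else {
    convs <- mapply(conversion_curve, curves, baselines, SIMPLIFY = FALSE)
    fits <- lapply(alphas, function(al) {
      T_C <- vapply(convs, temperature_at_alpha, numeric(1), level = al)
      ofw_fit(rates, T_C + 273.15)
    })
    lab <- alphas
  }
  out <- data.frame(
    alpha = lab,
    slope_a = vapply(fits, `[[`, numeric(1), "slope_a"),
    intercept_b = vapply(fits, `[[`, numeric(1), "intercept_b"),
    Ea_kJ_mol = vapply(fits, `[[`, numeric(1), "Ea"),
    A_pre_min = vapply(fits, `[[`, numeric(1), "A_pre"),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared")
  )
  attr(out, "fits") <- fits
  out
}

#' Write an isoconversional kinetics results CSV
#'
#' @param profile Output of [ea_profile()].
#' @param path File path.
#' @param sample Sample label written in the first column.
#' @export
write_kinetics_csv <- function(profile, path, sample = "sample") {
  df <- cbind(sample = sample, profile)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
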
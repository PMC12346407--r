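#' Configuration for the synthetic oxidation-exotherm generator
#'
#' Emulates non-isothermal DSC scans of a fat under oxygen at a linear heating
#' rate: an nth-order Arrhenius reaction integrated over temperature,
#' `dalpha/dT = (A/beta) * exp(-Ea/(R*T)) * (1-alpha)^n`, rendered as a
#' heat-flow exotherm on a sloping instrument baseline. Defaults place the
#' exotherm near 240 degC at 10 K/min with an activation energy typical of
#' lard oxidation.
#'
#' @param Ea_true Activation energy, kJ/mol (> 0).
#' @param logA_true log10 of the pre-exponential factor, A in 1/min.
#' @param reaction_order Reaction order n (default 1; the isoconversional
#'   analysis downstream does not assume one).
#' @param exotherm_height Heat-flow amplitude multiplying dalpha/dT
#'   (instrument units per 1/K).
#' @param baseline_intercept,baseline_slope Linear baseline (units, units/degC).
#' @param noise_sd Gaussian noise SD, heat-flow units.
#' @param T_min,T_max,T_step Temperature grid, degC. The kinetic ODE is
#'   integrated with a classical fourth-order Runge-Kutta scheme at the fixed
#'   grid step (reproducible, no adaptive stepping).
#' @param heating_rates Heating rates in K/min, positive and distinct.
#' @return A `dsc_sim_config` list.
#' @export
dsc_sim_config <- function(Ea_true = 95, logA_true = 9.3,
                           reaction_order = 1,
                           exotherm_height = 120,
                           baseline_intercept = 0.2, baseline_slope = 0.002,
                           noise_sd = 0.01,
                           T_min = 35, T_max = 300, T_step = 0.1,
                           heating_rates = c(5, 7.5, 10, 15)) {
  if (Ea_true <= 0) abort_domain("Ea_true must be positive (kJ/mol)")
  if (reaction_order <= 0) abort_domain("reaction_order must be positive")
  if (T_step <= 0 || T_max <= T_min) abort_domain("temperature grid must be strictly increasing")
  if (any(heating_rates <= 0)) abort_domain("heating rates must be positive")
  if (anyDuplicated(heating_rates)) abort_domain("heating rates must be distinct")
  if (noise_sd < 0) abort_domain("noise_sd must be non-negative")
  structure(list(
    Ea_true = Ea_true, logA_true = logA_true, reaction_order = reaction_order,
    exotherm_height = exotherm_height,
    baseline_intercept = baseline_intercept, baseline_slope = baseline_slope,
    noise_sd = noise_sd,
    T_min = T_min, T_max = T_max, T_step = T_step,
    heating_rates = heating_rates
  ), class = "dsc_sim_config")
}

# RK4 integration of dalpha/dT on the fixed temperature grid (in kelvin).
# Returns alpha at each grid point plus the rate dalpha/dT.
integrate_conversion <- function(T_K, Ea_J, A_min, beta, n) {
  rate <- function(TK, alpha) {
    (A_min / beta) * exp(-Ea_J / (GAS_CONSTANT * TK)) * max(0, 1 - alpha)^n
  }
  m <- length(T_K)
  alpha <- numeric(m)
  h <- T_K[2L] - T_K[1L]
  for (i in seq_len(m - 1L)) {
    a <- alpha[i]; Ti <- T_K[i]
    k1 <- rate(Ti, a)
    k2 <- rate(Ti + h / 2, a + h * k1 / 2)
    k3 <- rate(Ti + h / 2, a + h * k2 / 2)
    k4 <- rate(Ti + h, a + h * k3)
    alpha[i + 1L] <- min(1, a + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6)
  }
  dadT <- vapply(seq_len(m), function(i) rate(T_K[i], alpha[i]), numeric(1))
  list(alpha = alpha, dadT = dadT)
}

#' Simulate a DSC oxidation curve at one heating rate
#'
#' @param heating_rate Heating rate in K/min (> 0).
#' @param config A [dsc_sim_config()].
#' @param seed RNG seed for the noise draw.
#' @return A `dsc_curve` carrying attributes `alpha_true` and `dadT_true`
#'   (the generator's noise-free conversion and rate, used as ground truth in
#'   tests) and `config`.
#' @export
simulate_dsc_curve <- function(heating_rate, config = dsc_sim_config(), seed = NULL) {
  if (!is.numeric(heating_rate) || length(heating_rate) != 1L || heating_rate <= 0) {
    abort_domain("`heating_rate` must be a single positive number (K/min)")
  }
  temp_C <- seq(config$T_min, config$T_max, by = config$T_step)
  T_K <- temp_C + 273.15
  kin <- integrate_conversion(T_K, config$Ea_true * 1000, 10^config$logA_true,
                              heating_rate, config$reaction_order)
  hf <- config$exotherm_height * kin$dadT +
    config$baseline_intercept + config$baseline_slope * temp_C
  if (config$noise_sd > 0) {
    hf <- hf + with_seed(seed, stats::rnorm(length(hf), 0, config$noise_sd))
  }
  out <- dsc_curve(temp_C, hf, heating_rate)
  attr(out, "alpha_true") <- kin$alpha
  attr(out, "dadT_true") <- kin$dadT
  attr(out, "config") <- config
  out
}

#' Simulate the full heating-rate set
#'
#' One curve per configured heating rate, with per-curve sub-seeds derived
#' deterministically from `seed`.
#'
#' @inheritParams simulate_dsc_curve
#' @return A named list of `dsc_curve` objects (names = heating rates).
#' @export
simulate_dsc_set <- function(config = dsc_sim_config(), seed = NULL) {
  curves <- lapply(seq_along(config$heating_rates), function(i) {
    simulate_dsc_curve(config$heating_rates[i], config, derive_seed(seed, i))
  })
  names(curves) <- as.character(config$heating_rates)
  curves
}
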
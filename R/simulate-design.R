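#' Configuration for the synthetic design-table generator
#'
#' Generates a (concentration, time) factorial response table from known
#' second-order polynomial coefficients plus Gaussian noise, so that
#' response-surface fitting can be tested against exact ground truth.
#' Responses follow `Y = b0 + b1*X1 + b2*X2 + b3*X1^2 + b4*X2^2 + b5*X1*X2`.
#'
#' Default coefficients and noise SDs are representative of an
#' antioxidant-enriched lard storage study: onset temperature near 238 degC
#' rising ~3 degC per mg/g with mild curvature, activation energy near
#' 93 kJ/mol, peroxide value climbing with storage day, and a TBA index two
#' orders of magnitude smaller than PV.
#'
#' @param beta_true Named list of length-6 coefficient vectors
#'   (b0, b1, b2, b3, b4, b5 in natural units), one per response column.
#' @param design_points Data frame with columns `conc_mg_g` (mg/g) and
#'   `time_days` (days). Defaults to the packaged 24-run design layout.
#' @param noise_sd Named numeric vector of per-response noise SDs.
#' @param seed Integer seed used when the table is simulated.
#' @return A `design_sim_config` list.
#' @export
design_sim_config <- function(beta_true = NULL, design_points = NULL,
                              noise_sd = NULL, seed = NULL) {
  if (is.null(beta_true)) {
    beta_true <- list(
      To_C       = c(238.02, 3.17, 0.85, -0.66, -0.032, -0.033),
      Ea_kJ_mol  = c(92.55, 7.55, -0.63, -0.91, 0.026, -0.095),
      PV_meqO2_kg = c(2.49, -0.09, 0.45, 0.02, -0.0027, -0.017),
      TBA        = c(0.019, 0.0064, 0.0009, -4e-04, 0, -1e-04)
    )
  }
  if (is.null(design_points)) {
    dt <- design_table7()
    design_points <- data.frame(conc_mg_g = dt$conc_mg_g, time_days = dt$time_days)
  }
  if (is.null(noise_sd)) {
    noise_sd <- c(To_C = 1.68, Ea_kJ_mol = 2.90, PV_meqO2_kg = 0.38, TBA = 0.0027)
  }
  if (nrow(design_points) == 0L) abort_domain("design_points must be non-empty")
  if (!all(c("conc_mg_g", "time_days") %in% names(design_points))) {
    abort_domain("design_points needs columns conc_mg_g and time_days")
  }
  bad <- vapply(beta_true, function(b) length(b) != 6L, logical(1))
  if (any(bad)) abort_domain("each beta_true entry must have 6 coefficients")
  noise_sd <- noise_sd[names(beta_true)]
  noise_sd[is.na(noise_sd)] <- 0
  names(noise_sd) <- names(beta_true)
  if (any(noise_sd < 0)) abort_domain("noise_sd must be non-negative")
  structure(list(beta_true = beta_true, design_points = design_points,
                 noise_sd = noise_sd, seed = seed),
            class = "design_sim_config")
}

#' Simulate a design table from known polynomial ground truth
#'
#' @param config A [design_sim_config()].
#' @return A `design_table` whose response columns equal the polynomial
#'   evaluated at each design point plus Gaussian noise; the generating
#'   coefficients are attached as attribute `beta_true`.
#' @export
simulate_design <- function(config = design_sim_config()) {
  stopifnot(inherits(config, "design_sim_config"))
  X <- quadratic_design_matrix(config$design_points$conc_mg_g,
                               config$design_points$time_days)
  out <- config$design_points
  sim <- function() {
    for (resp in names(config$beta_true)) {
      y <- drop(X %*% config$beta_true[[resp]])
      if (config$noise_sd[[resp]] > 0) {
        y <- y + stats::rnorm(length(y), 0, config$noise_sd[[resp]])
      }
      out[[resp]] <<- y
    }
  }
  with_seed(config$seed, sim())
  for (col in setdiff(RESPONSE_COLS, names(out))) out[[col]] <- NA_real_
  tab <- design_table(out[, intersect(DESIGN_COLS, names(out))])
  attr(tab, "beta_true") <- config$beta_true
  tab
}
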
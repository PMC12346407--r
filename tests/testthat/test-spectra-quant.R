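# Derivative spectrophotometry: derivatives, windowed features, calibration,
# inversion and degradation kinetics.

wl_grid <- seq(350, 600, 0.5)

test_that("first derivative is exact for low-order polynomials", {
  lin <- ax_spectrum(wl_grid, 0.002 * wl_grid + 0.1)
  d <- first_derivative(lin)
  expect_equal(d$absorbance, rep(0.002, length(wl_grid)), tolerance = 1e-12)

  # any valid window/order combination
  d2 <- first_derivative(lin, smoothing_window = 21, poly_order = 3)
  expect_equal(d2$absorbance, rep(0.002, length(wl_grid)), tolerance = 1e-12)

  flat <- ax_spectrum(wl_grid, rep(0.37, length(wl_grid)))
  expect_equal(first_derivative(flat)$absorbance, rep(0, length(wl_grid)),
               tolerance = 1e-12)
})

test_that("derivative of a Gaussian band matches a dense finite-difference oracle", {
  band <- function(x) exp(-(x - 446)^2 / (2 * 144))
  sp <- ax_spectrum(wl_grid, band(wl_grid))
  d <- first_derivative(sp, smoothing_window = 11, poly_order = 4)
  fine <- seq(350, 600, 0.05)
  dd <- diff(band(fine)) / diff(fine)
  oracle <- stats::approx((fine[-1] + fine[-length(fine)]) / 2, dd, xout = wl_grid,
                          rule = 2)$y
  expect_lt(max(abs(d$absorbance - oracle)), 1e-4)
})

test_that("derivative rejects invalid smoothing parameters and non-spectra", {
  sp <- ax_spectrum(wl_grid, wl_grid * 0)
  expect_error(first_derivative(sp, smoothing_window = 10), class = "axstab_domain_error")
  expect_error(first_derivative(sp, smoothing_window = 3, poly_order = 2),
               class = "axstab_domain_error")
  expect_error(first_derivative(data.frame(a = 1)), class = "axstab_format_error")
  expect_error(ax_spectrum(c(350, 350.5, 351.6), c(1, 2, 3)), class = "axstab_format_error")
})

test_that("windowed areas follow closed forms", {
  ones <- ax_spectrum(wl_grid, rep(1, length(wl_grid)))
  d_ones <- first_derivative(ones)
  f <- extract_features(d_ones, ones, auc_integrand = "absorbance")
  expect_equal(f$auc1, 30, tolerance = 1e-12)   # window width
  expect_equal(f$auc2, 25, tolerance = 1e-12)

  ramp <- ax_spectrum(wl_grid, wl_grid / 1000)
  f2 <- extract_features(first_derivative(ramp), ramp, auc_integrand = "absorbance")
  expect_equal(f2$auc1, (450^2 - 420^2) / 2000, tolerance = 1e-12)  # = 13.05

  # with the derivative integrand, AUC over [420,450] equals A(450) - A(420)
  # up to the trapezoid quadrature error (h^2/12 * integral of |g''|)
  band <- function(x) exp(-(x - 446)^2 / (2 * 144))
  sp <- ax_spectrum(wl_grid, band(wl_grid))
  d <- first_derivative(sp, poly_order = 4)
  idx <- which(wl_grid >= 420 & wl_grid <= 450)
  g2 <- abs(diff(d$absorbance[idx], differences = 2)) / 0.5^2
  trap_bound <- (0.5^2 / 12) * sum(g2) * 0.5
  f3 <- extract_features(d, sp)
  expect_lt(abs(f3$auc1 - (band(450) - band(420))), trap_bound * 1.5)
})

test_that("feature windows outside the grid raise domain errors", {
  short <- ax_spectrum(seq(430, 600, 0.5), rep(1, 341))
  d <- first_derivative(short)
  expect_error(extract_features(d, short), class = "axstab_domain_error")
})

test_that("calibration matches the normal equations and flags degenerate designs", {
  # exact line: slope/intercept/R2 recovered to machine precision
  concs <- c(0.5, 1, 2, 3, 4)
  feats <- 0.2278 * concs + 0.0302
  cc <- calibrate(concs, feats, feature_kind = "AUC1", day = 0)
  expect_equal(cc$slope, 0.2278, tolerance = 1e-12)
  expect_equal(cc$intercept, 0.0302, tolerance = 1e-12)
  expect_equal(cc$r_squared, 1, tolerance = 1e-12)

  # random sets against the closed-form normal equations
  set.seed(31)
  for (r in 1:5) {
    x <- runif(10, 0, 4); y <- 0.3 * x + rnorm(10, 0, 0.05)
    got <- calibrate(x, y)
    want <- line_ols(x, y)
    expect_equal(got$slope, unname(want["slope"]), tolerance = 1e-10)
    expect_equal(got$intercept, unname(want["intercept"]), tolerance = 1e-10)
  }

  expect_warning(two <- calibrate(c(1, 2), c(0.1, 0.3)), "under-determined")
  expect_true(two$under_determined)
  expect_equal(two$r_squared, 1)
  expect_error(calibrate(c(2, 2, 2), c(1, 2, 3)), class = "axstab_singularity_error")
})

test_that("concentration estimation inverts the calibration", {
  cc <- calibrate(c(0.5, 1, 2, 3, 4), 0.2278 * c(0.5, 1, 2, 3, 4) + 0.0302)
  expect_equal(estimate_concentration(0.4858, cc), 2.0, tolerance = 1e-9)
  expect_equal(estimate_concentration(cc$intercept, cc), 0, tolerance = 1e-12)

  # round trip on noiseless synthetic spectra
  cfg <- quiet_spec_config()
  concs <- c(0.25, 0.5, 1, 2, 4)
  feats <- vapply(concs, function(c0) {
    sp <- simulate_spectrum(c0, 0, cfg)
    feature_vector(sp)[["AUC1"]]
  }, numeric(1))
  curve <- calibrate(concs, feats)
  expect_equal(estimate_concentration(feats, curve), concs, tolerance = 1e-9)

  zero_slope <- curve; zero_slope$slope <- 0
  expect_error(estimate_concentration(1, zero_slope), class = "axstab_singularity_error")
  expect_warning(est <- estimate_concentration(curve$intercept - 1, curve), "below zero")
  expect_true(est < 0)
})

test_that("first-order decay fits recover rate and initial level from log-linear data", {
  t <- c(0, 10, 30)
  conc <- 4 * exp(-0.005 * t)
  fit <- fit_first_order_decay(t, conc)
  expect_equal(fit$k, 0.005, tolerance = 1e-12)
  expect_equal(fit$c0, 4, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  flat <- fit_first_order_decay(c(0, 10, 30), c(2, 2, 2))
  expect_equal(flat$k, 0, tolerance = 1e-12)

  # 30-day retention at k = 0.005/day is exp(-0.15): the mid-teens-loss regime
  expect_equal(retention_percent(fit$c0 * exp(-fit$k * 30), fit$c0),
               100 * exp(-0.15), tolerance = 1e-9)
  expect_equal(retention_percent(3.44, 4.0), 86.0, tolerance = 1e-12)
  expect_equal(retention_percent(4.0, 4.0), 100)
  expect_equal(retention_percent(0, 4.0), 0)
  expect_error(retention_percent(1, 0), class = "axstab_domain_error")
  expect_error(fit_first_order_decay(c(0, 10), c(1, -1)), class = "axstab_domain_error")
})

test_that("low-noise synthetic series reach R2 >= 0.99 for every feature kind and slopes decay with storage", {
  cfg <- spectrum_sim_config(noise_sd = 1e-3)
  concs <- c(0.25, 0.5, 1, 1.5, 2, 3, 4)
  days <- c(0, 10, 30)
  spectra <- lapply(seq_along(days), function(d) {
    lapply(seq_along(concs), function(i) {
      simulate_spectrum(concs[i], days[d], cfg, seed = 100 * d + i)
    })
  })
  tab <- calibration_table(spectra, concs, days)
  expect_true(all(tab$r_squared >= 0.99))
  for (kind in unique(tab$feature_kind)) {
    slopes <- tab$slope[tab$feature_kind == kind][order(days)]
    expect_true(all(diff(slopes) < 0),
                label = sprintf("slope decline across days for %s", kind))
  }
})
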
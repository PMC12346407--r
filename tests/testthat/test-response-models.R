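# Second-order response-surface fitting, diagnostics, lack of fit, model
# reduction and summary-statistics group comparison.

test_that("the quadratic design matrix evaluates term by term", {
  tab <- design_table(data.frame(conc_mg_g = c(2, 0, 3.82), time_days = c(10, 0, 10),
                                 To_C = 0, Ea_kJ_mol = 0, PV_meqO2_kg = 0, TBA = 0))
  X <- build_design_matrix(tab)
  expect_equal(unname(X[1, ]), c(1, 2, 10, 4, 100, 20))
  expect_equal(unname(X[2, ]), c(1, 0, 0, 0, 0, 0))
  expect_equal(unname(X[3, ]), c(1, 3.82, 10, 14.5924, 100, 38.2))

  Xc <- build_design_matrix(tab, coded = TRUE)
  expect_true(all(abs(Xc[, "b1"]) <= 1 + 1e-12) && all(abs(Xc[, "b2"]) <= 1 + 1e-12))
})

test_that("noiseless polynomial data are interpolated exactly; random fits match the normal equations", {
  set.seed(91)
  b <- c(5, 1.5, -0.2, 0.3, 0.01, -0.05)
  x1 <- runif(12, 0, 4); x2 <- sample(c(0, 10, 30), 12, TRUE)
  tab <- design_table(data.frame(conc_mg_g = x1, time_days = x2,
                                 To_C = poly2(b, x1, x2), Ea_kJ_mol = 1,
                                 PV_meqO2_kg = 1, TBA = 1))
  fit <- fit_rsm(tab, "To")
  expect_equal(unname(fit$coefficients), b, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # noisy 8-point fit against the closed-form normal equations
  x1 <- c(0, 0.5, 1, 1.5, 2, 2.5, 3, 4); x2 <- c(0, 10, 30, 0, 10, 30, 0, 30)
  y <- poly2(b, x1, x2) + rnorm(8)
  tab2 <- design_table(data.frame(conc_mg_g = x1, time_days = x2, To_C = y,
                                  Ea_kJ_mol = 1, PV_meqO2_kg = 1, TBA = 1))
  fit2 <- fit_rsm(tab2, "To")
  X <- build_design_matrix(tab2)
  expect_equal(unname(fit2$coefficients), unname(normal_eq_ols(X, y)), tolerance = 1e-9)

  # residuals of an intercept-bearing OLS fit sum to zero
  expect_lt(abs(sum(fit2$residuals)), 1e-9)
})

test_that("small or degenerate designs are rejected", {
  six <- design_table(data.frame(conc_mg_g = 1:6, time_days = 1:6,
                                 To_C = rnorm(6), Ea_kJ_mol = 1, PV_meqO2_kg = 1, TBA = 1))
  expect_error(fit_rsm(six, "To"), class = "axstab_domain_error")

  # constant concentration makes X1 and X1^2 collinear with the intercept
  degen <- design_table(data.frame(conc_mg_g = rep(2, 10), time_days = rep(c(0, 10), 5),
                                   To_C = rnorm(10), Ea_kJ_mol = 1, PV_meqO2_kg = 1, TBA = 1))
  expect_error(fit_rsm(degen, "To"), class = "axstab_singularity_error")
})

test_that("R-squared is affine-invariant while coefficients rescale", {
  tab <- design_table7()
  f1 <- fit_rsm(tab, "To")
  tab2 <- tab
  tab2$To_C <- 3 * tab2$To_C - 100
  f2 <- fit_rsm(tab2, "To")
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-12)
  expect_equal(unname(f2$coefficients[-1]), 3 * unname(f1$coefficients[-1]),
               tolerance = 1e-9)
})

test_that("diagnostics follow both df conventions", {
  # perfect fit: adjusted and predicted R2 are 1
  b <- c(1, 2, 3, 4, 5, 6)
  x1 <- c(0, 0.5, 1, 1.5, 2, 2.5, 3, 4, 0.25, 3.5)
  x2 <- c(0, 10, 30, 0, 10, 30, 0, 30, 10, 0)
  tab <- design_table(data.frame(conc_mg_g = x1, time_days = x2,
                                 To_C = poly2(b, x1, x2),
                                 Ea_kJ_mol = 1, PV_meqO2_kg = 1, TBA = 1))
  m <- fit_rsm(tab, "To")
  expect_equal(m$adj_r_squared, 1, tolerance = 1e-9)
  expect_equal(m$pred_r_squared, 1, tolerance = 1e-6)

  # conventional F equals the standard ANOVA decomposition
  tabn <- tab; tabn$To_C <- tabn$To_C + c(0.1, -0.2, 0.05, 0.3, -0.1, 0.2, -0.3, 0.1, 0, -0.05)
  mn <- fit_rsm(tabn, "To")
  ssr <- mn$sst - mn$sse
  expect_equal(mn$F_model, (ssr / 5) / (mn$sse / (mn$n - 6)), tolerance = 1e-9)

  # as-published closed forms
  ap <- as_published_diagnostics(0.8315, 24)
  expect_equal(ap$F, 0.8315 * 22 / (1 - 0.8315), tolerance = 1e-12)
  ap2 <- diagnostics(mn, "as_published")
  expect_equal(ap2$adj_r_squared, 1 - (1 - mn$r_squared) * (mn$n - 1) / (mn$n - 2),
               tolerance = 1e-12)
})

test_that("lack of fit partitions the residual SS against a hand oracle", {
  set.seed(12)
  pts <- expand.grid(conc_mg_g = c(0, 1, 2, 4), time_days = c(0, 10, 30))
  pts <- pts[rep(seq_len(nrow(pts)), each = 2), ]  # duplicate every design point
  y <- poly2(c(10, 1, 0.2, -0.1, 0.01, -0.02), pts$conc_mg_g, pts$time_days) +
    rnorm(nrow(pts), 0, 0.5)
  tab <- design_table(cbind(pts, To_C = y, Ea_kJ_mol = 1, PV_meqO2_kg = 1, TBA = 1))
  m <- fit_rsm(tab, "To")
  lf <- lack_of_fit(m)
  expect_true(lf$computable)

  # oracle: direct partition
  key <- paste(pts$conc_mg_g, pts$time_days)
  ss_pe <- sum(tapply(y, key, function(v) sum((v - mean(v))^2)))
  df_pe <- length(y) - length(unique(key))
  ss_lof <- m$sse - ss_pe
  df_lof <- m$df_error - df_pe
  expect_equal(lf$F, (ss_lof / df_lof) / (ss_pe / df_pe), tolerance = 1e-9)
  expect_equal(lf$ss_pe, ss_pe, tolerance = 1e-9)

  # no replicates: flagged, not an error
  lf24 <- lack_of_fit(fit_rsm(design_table7(), "To"))
  expect_false(lf24$computable)

  # replicated perfect-fit data: zero lack-of-fit SS
  y2 <- poly2(c(10, 1, 0.2, -0.1, 0.01, -0.02), pts$conc_mg_g, pts$time_days)
  y2 <- y2 + rep(c(-0.1, 0.1), nrow(pts) / 2)  # pure replicate scatter only
  tab2 <- design_table(cbind(pts, To_C = y2, Ea_kJ_mol = 1, PV_meqO2_kg = 1, TBA = 1))
  lf2 <- lack_of_fit(fit_rsm(tab2, "To"))
  expect_equal(lf2$ss_lof, 0, tolerance = 1e-9)
})

test_that("backward elimination drops terms by significance", {
  # all terms overwhelmingly significant: model unchanged
  set.seed(5)
  b <- c(10, 3, 2, 1, 0.5, 0.8)
  x1 <- runif(40, 0, 4); x2 <- sample(c(0, 10, 30), 40, TRUE)
  tab <- design_table(data.frame(conc_mg_g = x1, time_days = x2,
                                 To_C = poly2(b, x1, x2) + rnorm(40, 0, 0.01),
                                 Ea_kJ_mol = 1, PV_meqO2_kg = 1, TBA = 1))
  red <- reduce_model(fit_rsm(tab, "To"))
  expect_identical(attr(red, "dropped"), character(0))

  # interaction absent from the truth: dropped in most replicates
  drops <- vapply(1:40, function(r) {
    set.seed(200 + r)
    y <- poly2(c(10, 3, 2, 1, 0.5, 0), x1, x2) + rnorm(40, 0, 1)
    tabr <- design_table(data.frame(conc_mg_g = x1, time_days = x2, To_C = y,
                                    Ea_kJ_mol = 1, PV_meqO2_kg = 1, TBA = 1))
    "b5" %in% attr(reduce_model(fit_rsm(tabr, "To")), "dropped")
  }, logical(1))
  expect_gt(mean(drops), 0.8)   # ~ 1 - alpha under the null for the b5 test

  # packaged design, onset response: the interaction is the least significant
  m <- fit_rsm(design_table7(), "To")
  p <- m$p_values[-1]
  expect_identical(names(which.max(p)), "b5")
  red24 <- reduce_model(m)
  expect_identical(attr(red24, "dropped")[1], "b5")

  # SSE increase on reduction is bounded by the dropped extra sum of squares
  expect_gte(red24$sse, m$sse - 1e-9)
})

test_that("reduced models predict with dropped terms at zero", {
  tab <- design_table7()
  m <- reduce_model(fit_rsm(tab, "PV"))
  beta <- stats::setNames(numeric(6), c("b0", "b1", "b2", "b3", "b4", "b5"))
  beta[m$terms] <- m$coefficients
  expect_equal(predict(m, 2, 10), unname(poly2(beta, 2, 10)), tolerance = 1e-12)

  z <- fit_rsm(tab, "To")
  z$coefficients[] <- 0
  expect_equal(predict(z, c(0, 2, 4), 10), c(0, 0, 0))
  z$coefficients[] <- c(1, 1, 0, 0, 0, 0)
  expect_equal(predict(z, 2, 0), 3)
})

test_that("coefficient confidence intervals attain nominal coverage on simulated designs", {
  b_true <- c(238.0207, 3.1688, 0.8542, -0.6562, -0.0317, -0.0333)
  base <- design_table7()
  sd_y <- fit_rsm(base, "To")$residual_se
  n_rep <- 500
  covered <- matrix(FALSE, n_rep, 6)
  for (r in seq_len(n_rep)) {
    cfg <- design_sim_config(beta_true = list(To_C = b_true),
                             noise_sd = c(To_C = sd_y), seed = 5000 + r)
    m <- fit_rsm(simulate_design(cfg), "To")
    half <- stats::qt(0.975, m$df_error) * m$standard_errors
    covered[r, ] <- abs(m$coefficients - b_true) <= half
  }
  cov <- colMeans(covered)
  mc_err <- 3 * sqrt(0.95 * 0.05 / n_rep)   # +/- 3 MC SEs around nominal
  expect_true(all(abs(cov - 0.95) <= mc_err))
})

test_that("Tukey letters from summary statistics match pairwise logic", {
  # identical groups share one letter
  g <- data.frame(label = c("a0", "a1", "a2"), mean = c(5, 5, 5),
                  sd = c(0.3, 0.3, 0.3), n = c(3, 3, 3))
  tl <- tukey_letters(g)
  expect_true(all(tl$letters$letters == "a"))

  # two groups 100 pooled SDs apart must separate
  g2 <- data.frame(label = c("lo", "hi"), mean = c(0, 100), sd = c(1, 1), n = c(3, 3))
  tl2 <- tukey_letters(g2)
  expect_setequal(tl2$letters$letters, c("a", "b"))

  # three groups against a brute-force pairwise oracle
  g3 <- data.frame(label = c("g1", "g2", "g3"), mean = c(10, 12, 30),
                   sd = c(1, 1, 1), n = c(4, 4, 4))
  tl3 <- tukey_letters(g3)
  mse <- mean(g3$sd^2)
  qc <- stats::qtukey(0.95, 3, sum(g3$n) - 3)
  sig <- function(i, j) abs(g3$mean[i] - g3$mean[j]) / sqrt(mse / 2 * (1/4 + 1/4)) > qc
  lst <- stats::setNames(tl3$letters$letters, tl3$letters$label)
  share <- function(a, b) {
    any(strsplit(lst[[a]], "")[[1]] %in% strsplit(lst[[b]], "")[[1]])
  }
  for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
    expect_identical(share(g3$label[pr[1]], g3$label[pr[2]]), !sig(pr[1], pr[2]))
  }

  expect_error(tukey_letters(data.frame(label = "x", mean = 1, sd = 0, n = 3)),
               class = "axstab_domain_error")
  expect_error(tukey_letters(data.frame(label = c("x", "y"), mean = 1:2,
                                        sd = c(0, 0), n = c(1, 3))),
               class = "axstab_domain_error")
})
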
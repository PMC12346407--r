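# Shared fixtures for the test suite; everything is generated in code.

# Noise-free spectrum generator config (keeps tests deterministic).
quiet_spec_config <- function(...) {
  spectrum_sim_config(noise_sd = 0, baseline_offset = 0, baseline_slope = 0, ...)
}

# Small, fast DSC config: coarser grid than the default but still resolving
# the exotherm; used where many curves are simulated.
fast_dsc_config <- function(...) {
  dsc_sim_config(T_step = 0.2, ...)
}

# Closed-form OLS for a straight line, used as a normal-equations oracle.
line_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Normal-equations oracle for an arbitrary design matrix.
normal_eq_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1L]
}

# The quadratic polynomial of the response-surface model, evaluated directly.
poly2 <- function(b, x1, x2) {
  b[1] + b[2] * x1 + b[3] * x2 + b[4] * x1^2 + b[5] * x2^2 + b[6] * x1 * x2
}
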
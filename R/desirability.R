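#' One-sided Derringer desirability specification
#'
#' Each response gets a goal (`maximize` or `minimize`), bounds `L < U`, a
#' shape exponent `s > 0` (1 = linear) and a weight for the geometric mean.
#'
#' @param goal `"maximize"` or `"minimize"`.
#' @param L,U Lower and upper bound in response units (`U > L`).
#' @param s Shape exponent (default 1).
#' @param weight Relative weight (default 1).
#' @return A `desirability_entry` list.
#' @export
desirability_entry <- function(goal = c("maximize", "minimize"), L, U,
                               s = 1, weight = 1) {
  goal <- match.arg(goal)
  if (U <= L) abort_domain("desirability bounds need U > L")
  if (s <= 0) abort_domain("shape exponent s must be positive")
  if (weight <= 0) abort_domain("weight must be positive")
  structure(list(goal = goal, L = L, U = U, s = s, weight = weight),
            class = "desirability_entry")
}

#' Default desirability specification from a design table
#'
#' Maximize onset temperature and activation energy, minimize peroxide and
#' TBA values, with bounds set to each response's observed range in the
#' table, linear shape and equal weights.
#'
#' @param table A `design_table`.
#' @return Named list of [desirability_entry()] objects (names `To`, `Ea`,
#'   `PV`, `TBA`).
#' @export
default_desirability_spec <- function(table) {
  stopifnot(inherits(table, "design_table"))
  mk <- function(resp, goal) {
    col <- resolve_response(table, resp)
    desirability_entry(goal, L = min(table[[col]]), U = max(table[[col]]))
  }
  list(To = mk("To", "maximize"), Ea = mk("Ea", "maximize"),
       PV = mk("PV", "minimize"), TBA = mk("TBA", "minimize"))
}

#' Per-response desirability transform
#'
#' `maximize`: `d = clip(((y - L)/(U - L))^s, 0, 1)`;
#' `minimize`: `d = clip(((U - y)/(U - L))^s, 0, 1)`.
#'
#' @param y Response value(s).
#' @param entry A [desirability_entry()].
#' @return Desirability in [0, 1], vectorized over `y`.
#' @export
desirability_value <- function(y, entry) {
  stopifnot(inherits(entry, "desirability_entry"))
  u <- if (entry$goal == "maximize") {
    (y - entry$L) / (entry$U - entry$L)
  } else {
    (entry$U - y) / (entry$U - entry$L)
  }
  pmin(1, pmax(0, u))^entry$s
}

#' Overall desirability
#'
#' Weighted geometric mean `D = (prod d_i^w_i)^(1/sum w_i)`; any zero
#' component forces `D = 0`.
#'
#' @param d_values Per-response desirabilities in [0, 1].
#' @param weights Positive weights (default equal).
#' @return Scalar D in [0, 1].
#' @export
overall_desirability <- function(d_values, weights = rep(1, length(d_values))) {
  if (length(weights) != length(d_values)) {
    abort_domain("`weights` must match `d_values` in length")
  }
  if (any(weights < 0)) abort_domain("weights must be non-negative")
  if (any(d_values < 0 | d_values > 1)) abort_domain("desirabilities must lie in [0, 1]")
  if (any(d_values == 0)) return(0)
  exp(sum(weights * log(d_values)) / sum(weights))
}

#' Optimal antioxidant concentration by desirability
#'
#' Evaluates the overall desirability of the four fitted response surfaces on
#' a concentration grid and returns the maximizer. With
#' `time_handling = "averaged"` (default) the profile at each concentration is
#' the mean of D over the study's storage days, reflecting a single
#' recommended concentration "during storage"; `"fixed"` evaluates at one
#' time point. Ties break toward the lower concentration.
#'
#' @param models Named list of `rsm_model` objects; names must match the
#'   spec's names.
#' @param spec Named list of [desirability_entry()] objects, e.g.
#'   [default_desirability_spec()] output.
#' @param grid_step Concentration grid step, mg/g (default 0.01).
#' @param conc_range Search interval, mg/g (default 0 to 4).
#' @param time_handling `"averaged"` or `"fixed"`.
#' @param times Storage days averaged over (default 0, 10, 30).
#' @param fixed_time Evaluation day when `time_handling = "fixed"`.
#' @return A `desirability_result`: `optimal_concentration`, `optimal_D`,
#'   `D_profile` (data frame `conc_mg_g`, `D`, and per-response d columns),
#'   `per_response_d` at the optimum, `time_handling`.
#' @export
optimize_concentration <- function(models, spec, grid_step = 0.01,
                                   conc_range = c(0, 4),
                                   time_handling = c("averaged", "fixed"),
                                   times = c(0, 10, 30), fixed_time = 30) {
  time_handling <- match.arg(time_handling)
  if (grid_step <= 0) abort_domain("grid_step must be positive")
  if (!length(spec) || is.null(names(spec))) abort_domain("`spec` must be a named list")
  missing <- setdiff(names(spec), names(models))
  if (length(missing)) {
    abort_domain(sprintf("no fitted model for response(s): %s", paste(missing, collapse = ", ")))
  }
  grid <- seq(conc_range[1], conc_range[2], by = grid_step)
  if (!length(grid)) abort_domain("empty concentration grid")
  eval_times <- if (time_handling == "averaged") times else fixed_time
  weights <- vapply(spec, `[[`, numeric(1), "weight")

  # d per response, averaged over evaluation times, plus the time-wise D mean
  d_mat <- matrix(0, length(grid), length(spec),
                  dimnames = list(NULL, names(spec)))
  D <- numeric(length(grid))
  for (t2 in eval_times) {
    d_t <- vapply(names(spec), function(r) {
      desirability_value(predict(models[[r]], grid, t2), spec[[r]])
    }, numeric(length(grid)))
    d_t <- matrix(d_t, nrow = length(grid), dimnames = list(NULL, names(spec)))
    D <- D + apply(d_t, 1L, overall_desirability, weights = weights)
    d_mat <- d_mat + d_t
  }
  D <- D / length(eval_times)
  d_mat <- d_mat / length(eval_times)

  best <- which.max(D)  # first maximum = lowest concentration on ties
  profile <- data.frame(conc_mg_g = grid, D = D)
  for (r in names(spec)) profile[[paste0("d_", r)]] <- d_mat[, r]
  structure(list(
    optimal_concentration = grid[best],
    optimal_D = D[best],
    D_profile = profile,
    per_response_d = d_mat[best, ],
    time_handling = time_handling,
    times = eval_times
  ), class = "desirability_result")
}

#' @export
print.desirability_result <- function(x, ...) {
  cat(sprintf(
    "<desirability_result> optimal concentration = %.2f mg/g (D = %.4f, time %s over {%s})\n",
    x$optimal_concentration, x$optimal_D, x$time_handling,
    paste(x$times, collapse = ", ")
  ))
  cat("  per-response d at optimum:",
      paste(sprintf("%s = %.3f", names(x$per_response_d), x$per_response_d),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write the desirability profile CSV
#'
#' @param result A `desirability_result`.
#' @param path File path.
#' @export
write_desirability_csv <- function(result, path) {
  stopifnot(inherits(result, "desirability_result"))
  utils::write.csv(result$D_profile, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
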
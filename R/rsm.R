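# Second-order response-surface modelling: full quadratic fits in natural
# units, inference panels, dual df conventions, lack-of-fit partition and
# backward term elimination.

TERM_NAMES <- c("b0", "b1", "b2", "b3", "b4", "b5")
TERM_LABELS <- c("1", "X1", "X2", "X1^2", "X2^2", "X1*X2")

quadratic_design_matrix <- function(X1, X2) {
  m <- cbind(1, X1, X2, X1^2, X2^2, X1 * X2)
  colnames(m) <- TERM_NAMES
  m
}

# Center-and-scale coding of a factor column to [-1, 1].
code_factor <- function(x) {
  half <- (max(x) - min(x)) / 2
  if (half == 0) abort_singular("cannot code a constant factor")
  (x - (max(x) + min(x)) / 2) / half
}

#' Build the second-order model matrix
#'
#' Columns, in fixed order: intercept, X1, X2, X1^2, X2^2, X1*X2 where X1 is
#' concentration (mg/g) and X2 is time (days). Natural (uncoded) units by
#' default; `coded = TRUE` centers and scales each factor to [-1, 1] before
#' forming powers.
#'
#' @param table A `design_table`.
#' @param coded Use coded factor levels instead of natural units.
#' @return Numeric matrix with `nrow(table)` rows and 6 columns.
#' @export
build_design_matrix <- function(table, coded = FALSE) {
  stopifnot(inherits(table, "design_table"))
  X1 <- table$conc_mg_g
  X2 <- table$time_days
  if (coded) {
    X1 <- code_factor(X1)
    X2 <- code_factor(X2)
  }
  quadratic_design_matrix(X1, X2)
}

#' Fit a second-order response-surface model
#'
#' Ordinary least squares of one response on the full quadratic polynomial in
#' concentration and time. Coefficient p-values are two-sided t-tests on the
#' residual degrees of freedom; R-squared is `1 - SSE/SST`.
#'
#' @param table A `design_table` (>= 7 rows for positive error df).
#' @param response Response column or alias (`"To"`, `"Ea"`, `"PV"`, `"TBA"`,
#'   `"Y1"`-`"Y4"`, or a canonical column name).
#' @param coded Fit on coded [-1, 1] factor levels instead of natural units.
#' @param terms Character subset of `c("b1","b2","b3","b4","b5")` to retain
#'   (the intercept is always kept); used by [reduce_model()].
#' @return An `rsm_model`.
#' @export
fit_rsm <- function(table, response, coded = FALSE,
                    terms = c("b1", "b2", "b3", "b4", "b5")) {
  stopifnot(inherits(table, "design_table"))
  col <- resolve_response(table, response)
  y <- table[[col]]
  if (anyNA(y)) abort_domain(sprintf("response '%s' contains missing values", col))
  keep <- c("b0", intersect(TERM_NAMES[-1L], terms))
  X <- build_design_matrix(table, coded = coded)[, keep, drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  if (n < p + 1L) {
    abort_domain(sprintf("need at least %d rows to fit %d terms with positive error df", p + 1L, p))
  }
  qr_X <- qr(X)
  if (qr_X$rank < p) abort_singular("rank-deficient design: model terms are confounded")
  fit <- stats::lm.fit(X, y)
  coefs <- fit$coefficients
  res <- fit$residuals
  df_e <- n - p
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  sigma2 <- sse / df_e
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtX_inv) * sigma2)
  tval <- coefs / se
  pval <- 2 * stats::pt(abs(tval), df_e, lower.tail = FALSE)
  r2 <- if (sst > 0) 1 - sse / sst else 1

  model <- structure(list(
    response = col, coded = coded,
    terms = keep,
    coefficients = stats::setNames(coefs, keep),
    standard_errors = stats::setNames(se, keep),
    t_statistics = stats::setNames(tval, keep),
    p_values = stats::setNames(pval, keep),
    r_squared = r2,
    residual_se = sqrt(sigma2),
    sse = sse, sst = sst, n = n, df_error = df_e,
    fitted = drop(X %*% coefs), residuals = res,
    X = X, y = y,
    data = table,
    df_convention = NA_character_
  ), class = "rsm_model")
  diagnostics(model, convention = "conventional")
}

#' Model-level diagnostics under two df conventions
#'
#' `"conventional"` uses the regression ANOVA degrees of freedom
#' (`df_model = p - 1`, `df_error = n - p`): adjusted R-squared
#' `1 - (1-R2)(n-1)/(n-p)`, `F = (SSR/df_model)/(SSE/df_error)`, and
#' predicted R-squared `1 - PRESS/SST` with leave-one-out PRESS computed from
#' the hat matrix. `"as_published"` is a simple-regression convention
#' (`df_model = 1`, `df_error = n - 2`) found in some published panels:
#' adjusted R-squared `1 - (1-R2)(n-1)/(n-2)` and `F = R2 (n-2)/(1-R2)`.
#'
#' @param model An `rsm_model`.
#' @param convention `"conventional"` (default) or `"as_published"`.
#' @return The model with `adj_r_squared`, `pred_r_squared`, `F_model`,
#'   `p_model`, `press` and `df_convention` filled in.
#' @export
diagnostics <- function(model, convention = c("conventional", "as_published")) {
  convention <- match.arg(convention)
  stopifnot(inherits(model, "rsm_model"))
  n <- model$n; p <- length(model$terms); r2 <- model$r_squared
  if (convention == "conventional") {
    if (n <= p) abort_domain("non-positive error df under the conventional convention")
    df_m <- p - 1L; df_e <- n - p
    adj <- 1 - (1 - r2) * (n - 1) / df_e
    ssr <- model$sst - model$sse
    Fv <- (ssr / df_m) / (model$sse / df_e)
    h <- stats::hat(model$X, intercept = FALSE)
    press <- sum((model$residuals / (1 - h))^2)
    pred <- if (model$sst > 0) 1 - press / model$sst else 1
  } else {
    if (n <= 2L) abort_domain("need n > 2 for the as-published convention")
    df_m <- 1L; df_e <- n - 2L
    ap <- as_published_diagnostics(r2, n)
    adj <- ap$adj_r_squared
    Fv <- ap$F
    press <- NA_real_
    pred <- NA_real_
  }
  model$adj_r_squared <- adj
  model$pred_r_squared <- pred
  model$press <- press
  model$F_model <- Fv
  model$p_model <- stats::pf(Fv, df_m, df_e, lower.tail = FALSE)
  model$df_model <- df_m
  model$df_error_diag <- df_e
  model$df_convention <- convention
  model
}

#' As-published diagnostic formulas
#'
#' The closed forms of the `df_model = 1 / df_error = n - 2` convention,
#' exposed so a reported R-squared can be converted directly:
#' `adj = 1 - (1-R2)(n-1)/(n-2)` and `F = R2 (n-2)/(1-R2)`.
#'
#' @param r_squared Coefficient of determination in [0, 1).
#' @param n Number of observations (> 2).
#' @return List with `adj_r_squared`, `F`.
#' @export
as_published_diagnostics <- function(r_squared, n) {
  if (any(r_squared < 0) || any(r_squared >= 1)) abort_domain("r_squared must lie in [0, 1)")
  if (n <= 2L) abort_domain("need n > 2")
  list(adj_r_squared = 1 - (1 - r_squared) * (n - 1) / (n - 2),
       F = r_squared * (n - 2) / (1 - r_squared))
}

#' Lack-of-fit test
#'
#' Partitions the residual sum of squares into pure error (within groups of
#' replicated design points) and lack of fit. Design points are grouped as
#' replicates when their (concentration, time) pairs agree within `tol`
#' (default exact equality). If no pure-error degrees of freedom exist the
#' test is flagged not computable rather than raising an error.
#'
#' @param model An `rsm_model`.
#' @param tol Absolute tolerance for replicate grouping.
#' @return A list: `computable`, and when computable `F`, `p`, `ss_lof`,
#'   `ss_pe`, `df_lof`, `df_pe`.
#' @export
lack_of_fit <- function(model, tol = 0) {
  stopifnot(inherits(model, "rsm_model"))
  tab <- model$data
  key <- if (tol <= 0) {
    paste(tab$conc_mg_g, tab$time_days)
  } else {
    paste(round(tab$conc_mg_g / tol), round(tab$time_days / tol))
  }
  groups <- split(seq_len(model$n), key)
  ss_pe <- sum(vapply(groups, function(idx) {
    sum((model$y[idx] - mean(model$y[idx]))^2)
  }, numeric(1)))
  df_pe <- model$n - length(groups)
  if (df_pe == 0L) {
    return(list(computable = FALSE,
                reason = "no replicated design points: pure-error df is zero"))
  }
  ss_lof <- model$sse - ss_pe
  df_lof <- model$df_error - df_pe
  if (df_lof <= 0L) {
    return(list(computable = FALSE,
                reason = "no lack-of-fit df: the model saturates the distinct design points"))
  }
  Fv <- (ss_lof / df_lof) / (ss_pe / df_pe)
  list(computable = TRUE, F = Fv,
       p = stats::pf(Fv, df_lof, df_pe, lower.tail = FALSE),
       ss_lof = ss_lof, ss_pe = ss_pe, df_lof = df_lof, df_pe = df_pe)
}

#' Backward elimination of non-significant terms
#'
#' Iteratively refits the model after dropping the least significant
#' non-intercept term with p above `alpha`, stopping when every retained term
#' is significant (or only the intercept remains). Model hierarchy is not
#' enforced by default: a quadratic term may outlive its linear parent;
#' `hierarchy = TRUE` protects linear terms while their quadratic or
#' interaction children remain.
#'
#' @param model An `rsm_model` (full or partial).
#' @param alpha Significance level for retention (default 0.05).
#' @param hierarchy Enforce weak model hierarchy.
#' @return The reduced `rsm_model`; the dropped terms (in removal order) are
#'   attached as attribute `dropped`.
#' @export
reduce_model <- function(model, alpha = 0.05, hierarchy = FALSE) {
  stopifnot(inherits(model, "rsm_model"))
  dropped <- character(0)
  current <- model
  repeat {
    nonint <- setdiff(current$terms, "b0")
    if (!length(nonint)) break
    p <- current$p_values[nonint]
    candidates <- names(p)[p > alpha]
    if (hierarchy) {
      protected <- c(
        if (any(c("b3", "b5") %in% nonint)) "b1",
        if (any(c("b4", "b5") %in% nonint)) "b2"
      )
      candidates <- setdiff(candidates, protected)
    }
    if (!length(candidates)) break
    worst <- candidates[which.max(p[candidates])]
    dropped <- c(dropped, worst)
    current <- fit_rsm(model$data, model$response, coded = model$coded,
                       terms = setdiff(nonint, worst))
  }
  attr(current, "dropped") <- dropped
  current
}

#' Predict from a response-surface model
#'
#' Evaluates the fitted polynomial; terms eliminated from a reduced model
#' contribute zero. Vectorized over `conc` and `time` (recycled to a common
#' length), so response-surface grids evaluate in one call.
#'
#' @param object An `rsm_model`.
#' @param conc Concentration(s), mg/g.
#' @param time Time(s), days.
#' @param ... Unused.
#' @return Numeric vector of predicted response values.
#' @export
predict.rsm_model <- function(object, conc, time, ...) {
  k <- max(length(conc), length(time))
  conc <- rep_len(conc, k); time <- rep_len(time, k)
  X1 <- conc; X2 <- time
  if (object$coded) {
    X1 <- code_factor_like(conc, object$data$conc_mg_g)
    X2 <- code_factor_like(time, object$data$time_days)
  }
  full <- quadratic_design_matrix(X1, X2)
  beta <- stats::setNames(numeric(6), TERM_NAMES)
  beta[object$terms] <- object$coefficients
  drop(full %*% beta)
}

code_factor_like <- function(x, ref) {
  half <- (max(ref) - min(ref)) / 2
  (x - (max(ref) + min(ref)) / 2) / half
}

#' @export
print.rsm_model <- function(x, ...) {
  cat(sprintf("<rsm_model: %s ~ second-order polynomial (%s units), n = %d>\n",
              x$response, if (x$coded) "coded" else "natural", x$n))
  tab <- data.frame(term = TERM_LABELS[match(x$terms, TERM_NAMES)],
                    estimate = x$coefficients,
                    se = x$standard_errors,
                    t = x$t_statistics,
                    p = x$p_values)
  rownames(tab) <- x$terms
  print(format(tab, digits = 5), ...)
  cat(sprintf("R2 = %.4f, adj R2 = %.4f (%s), residual SE = %.4f, F = %.4f\n",
              x$r_squared, x$adj_r_squared, x$df_convention, x$residual_se, x$F_model))
  invisible(x)
}

#' Coefficient/diagnostics panel for all four responses
#'
#' Fits the full quadratic model per response and assembles the panel:
#' one coefficient block (estimate, SE, t, p per term) and one diagnostics
#' block per response.
#'
#' @param table A `design_table`.
#' @param responses Response aliases to fit.
#' @param convention df convention for the diagnostics block.
#' @return A list with data frames `coefficients` and `diagnostics_table`,
#'   plus the fitted `models`.
#' @export
rsm_panel <- function(table, responses = c("To", "Ea", "PV", "TBA"),
                      convention = c("conventional", "as_published")) {
  convention <- match.arg(convention)
  models <- lapply(responses, function(r) {
    diagnostics(fit_rsm(table, r), convention = convention)
  })
  names(models) <- responses
  coef_rows <- do.call(rbind, lapply(responses, function(r) {
    m <- models[[r]]
    data.frame(response = r, term = m$terms,
               estimate = unname(m$coefficients),
               se = unname(m$standard_errors),
               t = unname(m$t_statistics),
               p = unname(m$p_values))
  }))
  lof <- lapply(models, lack_of_fit)
  diag_rows <- do.call(rbind, lapply(responses, function(r) {
    m <- models[[r]]; lf <- lof[[r]]
    data.frame(response = r, r_squared = m$r_squared,
               adj_r_squared = m$adj_r_squared,
               pred_r_squared = m$pred_r_squared,
               residual_se = m$residual_se,
               F_model = m$F_model, p_model = m$p_model,
               lack_of_fit_F = if (lf$computable) lf$F else NA_real_,
               lack_of_fit_p = if (lf$computable) lf$p else NA_real_,
               df_convention = m$df_convention)
  }))
  list(coefficients = coef_rows, diagnostics_table = diag_rows, models = models)
}
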
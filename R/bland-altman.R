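#' Bland-Altman agreement analysis
#'
#' Compares experimental values with model predictions pairwise: differences
#' `experimental - predicted` are summarized by their mean (the bias), the
#' sample SD (n-1 denominator), and the limits of agreement
#' `bias +/- 1.96 * SD`, within which about 95\% of differences are expected
#' to fall under normality.
#'
#' @param experimental,predicted Numeric vectors of equal length (>= 2).
#' @return An `agreement_result` with `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `fraction_within`, and a `data` frame (`mean`, `difference`)
#'   for plotting.
#' @export
bland_altman <- function(experimental, predicted) {
  if (length(experimental) != length(predicted)) {
    abort_domain("`experimental` and `predicted` must have equal length")
  }
  if (length(experimental) < 2L) abort_domain("need at least 2 pairs")
  diffs <- experimental - predicted
  bias <- mean(diffs)
  sd_diff <- stats::sd(diffs)
  loa_low <- bias - 1.96 * sd_diff
  loa_high <- bias + 1.96 * sd_diff
  structure(list(
    bias = bias, sd_diff = sd_diff,
    loa_low = loa_low, loa_high = loa_high,
    fraction_within = mean(diffs >= loa_low & diffs <= loa_high),
    n = length(diffs),
    data = data.frame(mean = (experimental + predicted) / 2, difference = diffs)
  ), class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "<agreement_result> bias = %.4g, SD of differences = %.4g\n  limits of agreement: [%.4g, %.4g], %.0f%% of %d pairs within\n",
    x$bias, x$sd_diff, x$loa_low, x$loa_high, 100 * x$fraction_within, x$n
  ))
  invisible(x)
}

#' Write a Bland-Altman CSV
#'
#' Per-pair means and differences plus the summary columns repeated on each
#' row.
#'
#' @param result An `agreement_result`.
#' @param path File path.
#' @export
write_bland_altman_csv <- function(result, path) {
  stopifnot(inherits(result, "agreement_result"))
  df <- result$data
  df$bias <- result$bias
  df$loa_low <- result$loa_low
  df$loa_high <- result$loa_high
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
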
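#' One-way ANOVA and Tukey letters from group summaries
#'
#' Works from summary statistics (mean, SD, n per group), the form in which
#' replicate assay results are usually tabulated. The pooled within-group mean
#' square feeds a one-way ANOVA F test and pairwise Tukey-Kramer comparisons
#' on the studentized-range distribution; groups are then labelled with a
#' compact letter display (groups sharing a letter are not significantly
#' different) using the insert-and-absorb algorithm.
#'
#' @param groups Data frame with columns `label`, `mean`, `sd`, `n`
#'   (each `n >= 2`).
#' @param alpha Family-wise significance level (default 0.05).
#' @return A `tukey_letters` list: `letters` (data frame `label`, `mean`,
#'   `letters`, ordered by decreasing mean), `anova` (F, df, p),
#'   `pairwise` (per-pair difference, critical value, significance) and the
#'   pooled `mse`.
#' @export
tukey_letters <- function(groups, alpha = 0.05) {
  req <- c("label", "mean", "sd", "n")
  if (!all(req %in% names(groups))) {
    abort_domain("`groups` needs columns label, mean, sd, n")
  }
  k <- nrow(groups)
  if (k < 2L) abort_domain("need at least 2 groups")
  if (any(groups$n < 2L)) abort_domain("every group needs n >= 2 replicates")
  if (any(groups$sd < 0)) abort_domain("group SDs must be non-negative")
  N <- sum(groups$n)
  df_w <- N - k
  grand <- sum(groups$n * groups$mean) / N
  ss_b <- sum(groups$n * (groups$mean - grand)^2)
  ss_w <- sum((groups$n - 1) * groups$sd^2)
  mse <- ss_w / df_w
  Fv <- if (mse > 0) (ss_b / (k - 1)) / mse else Inf
  p_anova <- stats::pf(Fv, k - 1, df_w, lower.tail = FALSE)

  pairs <- utils::combn(k, 2)
  q_crit <- stats::qtukey(1 - alpha, k, df_w)
  pw <- data.frame(
    i = groups$label[pairs[1, ]], j = groups$label[pairs[2, ]],
    diff = groups$mean[pairs[1, ]] - groups$mean[pairs[2, ]]
  )
  pw$se <- sqrt(mse / 2 * (1 / groups$n[pairs[1, ]] + 1 / groups$n[pairs[2, ]]))
  pw$q <- ifelse(pw$se > 0, abs(pw$diff) / pw$se, ifelse(pw$diff == 0, 0, Inf))
  pw$significant <- pw$q > q_crit

  ord <- order(-groups$mean)
  sig_pairs <- cbind(match(pairs[1, ], ord), match(pairs[2, ], ord))[pw$significant, , drop = FALSE]
  letters <- cld_insert_absorb(k, sig_pairs)

  structure(list(
    letters = data.frame(label = groups$label[ord], mean = groups$mean[ord],
                         letters = letters),
    anova = list(F = Fv, df1 = k - 1, df2 = df_w, p = p_anova),
    pairwise = pw, mse = mse, q_critical = q_crit, alpha = alpha
  ), class = "tukey_letters")
}

# Insert-and-absorb compact letter display. `sig_pairs` is a 2-column matrix
# of group indices (in display order) that differ significantly. Returns one
# letter string per group.
cld_insert_absorb <- function(k, sig_pairs) {
  cols <- list(seq_len(k))   # each column = set of groups sharing a letter
  if (nrow(sig_pairs)) {
    for (r in seq_len(nrow(sig_pairs))) {
      i <- sig_pairs[r, 1]; j <- sig_pairs[r, 2]
      viol <- which(vapply(cols, function(cc) i %in% cc && j %in% cc, logical(1)))
      if (!length(viol)) next
      # split every violating column into a copy without i and one without j
      newcols <- list()
      for (ci in viol) {
        newcols <- c(newcols, list(setdiff(cols[[ci]], i)), list(setdiff(cols[[ci]], j)))
      }
      cols <- c(cols[-viol], newcols)
      cols <- cols[vapply(cols, length, integer(1)) > 0]
      # absorb columns that are subsets of another column
      drop <- rep(FALSE, length(cols))
      for (a in seq_along(cols)) {
        for (b in seq_along(cols)) {
          if (a == b || drop[a] || drop[b]) next
          if (all(cols[[a]] %in% cols[[b]]) &&
              (length(cols[[a]]) < length(cols[[b]]) || a > b)) {
            drop[a] <- TRUE
          }
        }
      }
      cols <- cols[!drop]
    }
  }
  # order columns by their highest-ranked member for a conventional display
  cols <- cols[order(vapply(cols, min, numeric(1)))]
  vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(cols, function(cc) g %in% cc, logical(1)))],
          collapse = "")
  }, character(1))
}

#' @export
print.tukey_letters <- function(x, ...) {
  cat(sprintf("<tukey_letters> one-way ANOVA F(%d, %d) = %.3f, p = %.4g; q* = %.3f\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p, x$q_critical))
  print(x$letters, row.names = FALSE)
  invisible(x)
}
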
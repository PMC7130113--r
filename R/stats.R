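new_toj_test <- function(statistic, df, p_value, estimate = NA_real_,
                         ci_low = NA_real_, ci_high = NA_real_, method) {
  structure(
    list(statistic = unname(statistic), df = unname(df),
         p_value = unname(p_value), estimate = unname(estimate),
         ci_low = unname(ci_low), ci_high = unname(ci_high), method = method),
    class = "toj_test"
  )
}

#' @export
print.toj_test <- function(x, ...) {
  cat(sprintf("%s\nstatistic = %.4f, df = %s, p = %.4g\n", x$method,
              x$statistic, paste(format(x$df), collapse = ", "), x$p_value))
  if (!is.na(x$estimate)) {
    cat(sprintf("estimate = %.4f, 95%% CI [%.4f, %.4f]\n",
                x$estimate, x$ci_low, x$ci_high))
  }
  invisible(x)
}

#' Pearson chi-squared test for equality of two proportions
#'
#' The 2x2 Pearson chi-square without continuity correction
#' (`chi^2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, df = 1), as used to
#' compare the proportion of excluded PSS values between postures. With 10
#' of 45 crossed and 0 of 45 uncrossed values excluded this gives exactly
#' 11.25.
#'
#' @param k1,n1 Successes and trials in the first sample.
#' @param k2,n2 Successes and trials in the second sample.
#' @return A `toj_test` with the chi-squared statistic, df = 1, p-value and
#'   the difference in proportions as estimate (no CI).
#' @export
#' @examples
#' chi_square_equal_prop(10, 45, 0, 45)$statistic  # 11.25
chi_square_equal_prop <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0 || k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2) {
    stop("need 0 <= k_i <= n_i with n_i > 0", call. = FALSE)
  }
  k <- k1 + k2
  if (k == 0 || k == n1 + n2) {
    stop("degenerate 2x2 table: a success/failure margin is empty",
         call. = FALSE)
  }
  # small-count warnings concern the chi-square approximation of the
  # p-value, not the statistic; the statistic itself is exact
  pt <- suppressWarnings(
    stats::prop.test(c(k1, k2), c(n1, n2), correct = FALSE))
  new_toj_test(pt$statistic, df = 1, p_value = pt$p.value,
               estimate = k1 / n1 - k2 / n2,
               method = "2-sample chi-squared test for equality of proportions")
}

#' One-sample t-test
#'
#' Tests whether the mean of `values` differs from `mu0` (two-sided), with
#' the 95\% confidence interval for the mean.
#'
#' @param values Numeric vector, at least two values with nonzero variance.
#' @param mu0 Null mean (default 0 ms, no prioritisation of either limb).
#' @return A `toj_test` with t, df = n - 1, p, mean estimate and 95% CI.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least two values", call. = FALSE)
  if (stats::var(values) == 0) {
    stop("zero variance: t statistic undefined", call. = FALSE)
  }
  tt <- stats::t.test(values, mu = mu0)
  new_toj_test(tt$statistic, df = tt$parameter, p_value = tt$p.value,
               estimate = tt$estimate, ci_low = tt$conf.int[1L],
               ci_high = tt$conf.int[2L], method = "one-sample t-test")
}

#' Paired-samples t-test
#'
#' One-sample t-test on the pairwise differences `a - b`.
#'
#' @param a,b Numeric vectors of equal length.
#' @return A `toj_test` on the mean difference.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length",
                                   call. = FALSE)
  out <- one_sample_t(a - b, mu0 = 0)
  out$method <- "paired-samples t-test"
  out
}

#' Reconstruct a t statistic from a printed mean and confidence interval
#'
#' Published one-sample t-tests are often reported only as a mean, a 95\%
#' confidence interval and degrees of freedom. Inverting the CI recovers the
#' standard error, `SE = (ci_high - ci_low) / (2 * qt(0.975, df))`, and hence
#' `t = mean / SE`, reproducing the printed t value up to rounding.
#'
#' @param mean Printed mean.
#' @param ci_low,ci_high Printed 95% CI bounds (`ci_low < ci_high`).
#' @param df Degrees of freedom.
#' @param mu0 Null value (default 0).
#' @return The t statistic.
#' @export
#' @examples
#' t_from_summary(-0.60, -31.80, 30.60, df = 13)  # approx -0.04
t_from_summary <- function(mean, ci_low, ci_high, df, mu0 = 0) {
  if (ci_low >= ci_high) stop("degenerate CI: need ci_low < ci_high",
                              call. = FALSE)
  if (df < 1) stop("`df` must be >= 1", call. = FALSE)
  se <- (ci_high - ci_low) / (2 * stats::qt(0.975, df))
  (mean - mu0) / se
}

#' Group-level one-sample t-tests on the analysis table
#'
#' Runs [one_sample_t()] against 0 ms on the included PSS values of every
#' group x posture cell.
#'
#' @param analysis_table A [build_analysis_table()] result.
#' @return Data frame with one row per group x posture: `n`, `mean_pss`,
#'   `t`, `df`, `p`, `ci_low`, `ci_high`.
#' @export
group_pss_tests <- function(analysis_table) {
  stopifnot(all(c("group", "posture", "pss_ms", "included") %in%
                  names(analysis_table)))
  tab <- analysis_table[analysis_table$included, , drop = FALSE]
  cells <- unique(tab[, c("group", "posture")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- tab$group == cells$group[i] & tab$posture == cells$posture[i]
    tt <- one_sample_t(tab$pss_ms[sel])
    data.frame(group = cells$group[i], posture = cells$posture[i],
               n = sum(sel), mean_pss = tt$estimate, t = tt$statistic,
               df = tt$df, p = tt$p_value, ci_low = tt$ci_low,
               ci_high = tt$ci_high, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$group, out$posture), , drop = FALSE]
}
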
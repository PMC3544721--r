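#' Replicate-level performance summary of an estimator
#'
#' Computes the simulation performance measures for one coefficient across
#' `S` replicates: bias (mean estimate minus truth), average estimated
#' standard error, standardised bias (bias divided by the average SE), mean
#' squared error, coverage (fraction of closed 95% intervals containing the
#' truth) and the Monte Carlo error of the bias, `SD(estimates) / sqrt(S)`.
#' Replicates flagged as excluded (e.g. logistic separation) are dropped
#' from every average, with the exclusion count reported.
#'
#' @param estimates,ses Numeric vectors of per-replicate point estimates and
#'   estimated SEs.
#' @param ci_low,ci_high Per-replicate confidence bounds (closed intervals).
#' @param truth The population-truth value of the coefficient.
#' @param excluded Logical vector flagging replicates to drop (default none).
#' @param coefficient Name carried through for reporting.
#' @return An object of class `performance_summary` (a one-row list):
#'   `coefficient`, `truth`, `bias`, `avg_se`, `std_bias`, `mse`, `coverage`,
#'   `mc_error_bias`, `n_replicates`, `n_excluded`.
#' @export
performance_summary <- function(estimates, ses, ci_low, ci_high, truth,
                                excluded = rep(FALSE, length(estimates)),
                                coefficient = "coef") {
  S0 <- length(estimates)
  stopifnot(length(ses) == S0, length(ci_low) == S0, length(ci_high) == S0,
            length(excluded) == S0)
  keep <- !excluded & is.finite(estimates) & is.finite(ses)
  est <- estimates[keep]; se <- ses[keep]
  lo <- ci_low[keep]; hi <- ci_high[keep]
  S <- length(est)
  if (S < 2L) stop("fewer than 2 usable replicates")
  bias <- mean(est) - truth
  avg_se <- mean(se)
  out <- list(coefficient = coefficient, truth = truth, bias = bias,
              avg_se = avg_se, std_bias = bias / avg_se,
              mse = mean((est - truth)^2),
              coverage = mean(lo <= truth & truth <= hi),
              mc_error_bias = stats::sd(est) / sqrt(S),
              n_replicates = S, n_excluded = S0 - S)
  class(out) <- "performance_summary"
  out
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("%s (truth %.4f, S = %d, excluded %d)\n", x$coefficient,
              x$truth, x$n_replicates, x$n_excluded))
  cat(sprintf("  bias %.4f (MC error %.4f), avg SE %.4f, std bias %.3f, MSE %.5f, coverage %.1f%%\n",
              x$bias, x$mc_error_bias, x$avg_se, x$std_bias, x$mse,
              100 * x$coverage))
  invisible(x)
}

#' @export
as.data.frame.performance_summary <- function(x, ...) {
  data.frame(coefficient = x$coefficient, truth = x$truth, bias = x$bias,
             avg_se = x$avg_se, std_bias = x$std_bias, mse = x$mse,
             coverage = x$coverage, mc_error_bias = x$mc_error_bias,
             n_replicates = x$n_replicates, n_excluded = x$n_excluded)
}

#' Precision comparison of complete-case versus multiple imputation
#'
#' Reports both the SE ratio `se_cc / se_mi` and the variance-scale gain
#' `(se_cc / se_mi)^2 - 1` (the relative increase in effective information;
#' under weak associations it is approximated by the fraction of incomplete
#' cases among those with the exposure observed). Both are reported because
#' verbal summaries of precision often mix the two scales.
#'
#' @param se_cc,se_mi Positive average standard errors from the
#'   complete-case and multiple-imputation analyses.
#' @return An object of class `precision_comparison`: `se_cc`, `se_mi`,
#'   `se_ratio`, `eq_gain`.
#' @export
precision_gain <- function(se_cc, se_mi) {
  if (any(c(se_cc, se_mi) <= 0) || any(!is.finite(c(se_cc, se_mi)))) {
    stop("standard errors must be positive and finite")
  }
  out <- list(se_cc = se_cc, se_mi = se_mi, se_ratio = se_cc / se_mi,
              eq_gain = (se_cc / se_mi)^2 - 1)
  class(out) <- "precision_comparison"
  out
}

#' @export
print.precision_comparison <- function(x, ...) {
  cat(sprintf("SE ratio CC/MI = %.3f (variance-scale gain %.3f)\n",
              x$se_ratio, x$eq_gain))
  invisible(x)
}

#' Monte Carlo acceptance band for empirical coverage
#'
#' The range within which the empirical coverage of nominal intervals should
#' fall (with 95% probability) when the true coverage equals the nominal
#' level: `nominal +/- 1.96 sqrt(nominal (1 - nominal) / S)`, in percent.
#'
#' @param S Number of simulation replicates.
#' @param nominal Nominal coverage (default 0.95).
#' @return Named numeric vector `c(low, high)` in percent.
#' @export
coverage_band <- function(S, nominal = 0.95) {
  if (S <= 0) stop("S must be positive")
  half <- 1.96 * sqrt(nominal * (1 - nominal) / S)
  c(low = 100 * (nominal - half), high = 100 * (nominal + half))
}
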
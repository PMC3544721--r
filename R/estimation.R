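# Analysis-model design shared by the linear and logistic fits:
# intercept, diet, log Wave I distress, race dummies, grade (linear),
# health and fitness as linear 1-5 scores.
analysis_design <- function(data) {
  cols <- c("diet", "ldistW1", "race1", "race2", "grade", "health", "fitness")
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("missing model columns: ", paste(miss, collapse = ", "))
  X <- cbind(`(Intercept)` = 1, as.matrix(data[, cols]))
  storage.mode(X) <- "double"
  X
}

new_fit_result <- function(coefficients, standard_errors, n_used,
                           converged = TRUE, separation_flag = FALSE,
                           model = "linear") {
  out <- list(coefficients = coefficients, standard_errors = standard_errors,
              n_used = n_used, converged = converged,
              separation_flag = separation_flag, model = model)
  class(out) <- "fit_result"
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit (n = %d%s%s)\n", x$model, x$n_used,
              if (!x$converged) ", NOT converged" else "",
              if (x$separation_flag) ", separation" else ""))
  print(round(rbind(coef = x$coefficients, se = x$standard_errors), 4))
  invisible(x)
}

#' Fit the linear analysis model
#'
#' Least-squares regression of log Wave II distress on diet, log Wave I
#' distress, the two race indicators, grade, health and fitness, with
#' model-based standard errors. Records with any missing model cell are
#' dropped, so applying this to an incomplete sample is exactly the
#' complete-case analysis.
#'
#' @param data A population/sample table.
#' @return A `fit_result` with named `coefficients` and `standard_errors`.
#' @export
fit_linear <- function(data) {
  y <- data$ldistW2
  if (is.null(y)) stop("column 'ldistW2' is required")
  X <- analysis_design(data)
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]
  y <- y[ok]
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("too few complete cases (", n, ") to fit the linear model")
  qrX <- qr(X)
  if (qrX$rank < p) {
    stop("rank-deficient design; collinear columns: ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1L):p]], collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / (n - p)
  XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot)]
  se <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
  names(se) <- names(beta) <- colnames(X)
  new_fit_result(beta, se, n, model = "linear")
}

#' Fit the logistic analysis model
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, convergence tolerance `1e-8`) of the depression indicator
#' `distW2i` on the same design as the linear model. A separation flag is
#' raised when the diet-by-outcome cross-tabulation has an empty cell, the
#' fit fails to converge, or fitted probabilities collapse to 0/1; flagged
#' replicates are excluded from performance summaries (with the exclusion
#' counted).
#'
#' @param data A population/sample table with `distW2i`.
#' @return A `fit_result` with `separation_flag`.
#' @export
fit_logistic <- function(data) {
  y <- data$distW2i
  if (is.null(y)) stop("column 'distW2i' is required")
  X <- analysis_design(data)
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]
  y <- y[ok]
  n <- nrow(X)
  if (n <= ncol(X)) stop("too few complete cases (", n, ") to fit the logistic model")
  # an empty cell in the exposure-by-outcome table is the operative
  # degeneracy; detect on the binary (or rounded imputed) diet indicator
  dbin <- as.integer(X[, "diet"] > 0.5)
  tab <- table(factor(dbin, levels = 0:1), factor(y, levels = 0:1))
  sep <- any(tab == 0L)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100L))
  )
  conv <- isTRUE(fit$converged)
  mu <- fit$fitted.values
  if (any(mu < 1e-10) || any(mu > 1 - 1e-10)) sep <- TRUE
  if (!conv || any(abs(fit$coefficients) > 50)) sep <- TRUE
  beta <- fit$coefficients
  # observed-information covariance from the final IRLS weights
  W <- fit$weights
  XtWX <- crossprod(X * sqrt(W))
  cov <- tryCatch(chol2inv(chol(XtWX)), error = function(e) {
    sep <<- TRUE
    matrix(NA_real_, ncol(X), ncol(X))
  })
  se <- sqrt(pmax(diag(cov), 0))
  names(se) <- names(beta) <- colnames(X)
  new_fit_result(beta, se, n, converged = conv, separation_flag = sep,
                 model = "logistic")
}

#' Pool multiply-imputed estimates by Rubin's rules
#'
#' Given the `m` per-imputation point estimates and squared standard errors
#' of one coefficient, computes the pooled estimate `q_bar` (their mean), the
#' within-imputation variance `W` (mean of the variances), the
#' between-imputation variance `B` (sample variance of the estimates), the
#' total variance `T = W + (1 + 1/m) B`, the classic Rubin degrees of freedom
#' `df = (m - 1) (1 + W / ((1 + 1/m) B))^2`, and the 95% confidence interval
#' `q_bar +/- t(df, 0.975) sqrt(T)`. When `B = 0` the degrees of freedom are
#' infinite and the interval uses the normal quantile.
#'
#' @param estimates Numeric vector of length `m >= 2`.
#' @param variances Matching vector of positive within-imputation variances
#'   (squared SEs).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `pooled_estimate`: list with `q_bar`, `W`,
#'   `B`, `T`, `df`, `se` (`sqrt(T)`), `ci_low`, `ci_high`, `m`.
#' @export
rubin_pool <- function(estimates, variances, conf_level = 0.95) {
  m <- length(estimates)
  if (m < 2L) stop("Rubin pooling requires m >= 2 imputations")
  if (length(variances) != m) stop("estimates and variances must have equal length")
  if (any(!is.finite(estimates)) || any(!is.finite(variances)) ||
      any(variances <= 0)) {
    stop("estimates must be finite and variances positive")
  }
  q_bar <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  Tv <- W + (1 + 1 / m) * B
  if (B > 0) {
    df <- (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
    tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  } else {
    df <- Inf
    Tv <- W
    tq <- stats::qnorm(1 - (1 - conf_level) / 2)
  }
  se <- sqrt(Tv)
  out <- list(q_bar = q_bar, W = W, B = B, T = Tv, df = df, se = se,
              ci_low = q_bar - tq * se, ci_high = q_bar + tq * se, m = m)
  class(out) <- "pooled_estimate"
  out
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("pooled estimate %.4f (SE %.4f), 95%% CI [%.4f, %.4f], df %.1f, m = %d\n",
              x$q_bar, x$se, x$ci_low, x$ci_high, x$df, x$m))
  invisible(x)
}

# Pool every coefficient of a list of fit_results; returns a data.frame
# (coefficient, estimate, se, ci_low, ci_high, df).
pool_fits <- function(fits, conf_level = 0.95) {
  cn <- names(fits[[1L]]$coefficients)
  est <- vapply(fits, function(f) f$coefficients, numeric(length(cn)))
  var <- vapply(fits, function(f) f$standard_errors^2, numeric(length(cn)))
  rows <- lapply(seq_along(cn), function(j) {
    p <- rubin_pool(est[j, ], var[j, ], conf_level)
    data.frame(coefficient = cn[j], estimate = p$q_bar, se = p$se,
               ci_low = p$ci_low, ci_high = p$ci_high, df = p$df)
  })
  do.call(rbind, rows)
}
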
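# Shared fixtures and independent oracles used across test files.

# A moderate population under the calibrated defaults, built once per run.
shared_pop <- local({
  pop <- NULL
  function(n = 2e5) {
    if (is.null(pop) || nrow(pop) < n) {
      pop <<- generate_population(population_config(population_size = n,
                                                    seed = 20120613L))
    }
    pop
  }
})

# Bivariate normal sample with MCAR missingness in the second column.
bivariate_mcar <- function(n, rho = 0.5, miss = 0.3) {
  y1 <- rnorm(n)
  y2 <- rho * y1 + sqrt(1 - rho^2) * rnorm(n)
  y2[runif(n) < miss] <- NA
  cbind(y1 = y1, y2 = y2)
}

# Closed-form proper Bayesian regression imputation for a monotone bivariate
# pattern: noninformative posterior from the complete cases, one parameter
# draw per call, predictive draws for the missing y2. Independent of the
# data-augmentation code path.
oracle_monotone_impute <- function(y1, y2, mis_idx) {
  obs <- setdiff(seq_along(y1), mis_idx)
  X <- cbind(1, y1[obs])
  yo <- y2[obs]
  n1 <- length(obs)
  XtXi <- solve(crossprod(X))
  bhat <- XtXi %*% crossprod(X, yo)
  rss <- sum((yo - X %*% bhat)^2)
  sig2 <- rss / rchisq(1, n1 - 2)
  b <- bhat + t(chol(sig2 * XtXi)) %*% rnorm(2)
  Xm <- cbind(1, y1[mis_idx])
  as.numeric(Xm %*% b + rnorm(length(mis_idx), 0, sqrt(sig2)))
}

# Simple-slope fit of y2 ~ y1 returning estimate and variance.
slope_fit <- function(Y) {
  ok <- stats::complete.cases(Y)
  f <- stats::lm.fit(cbind(1, Y[ok, 1L]), Y[ok, 2L])
  rss <- sum(f$residuals^2)
  n <- sum(ok)
  XtXi <- chol2inv(chol(crossprod(cbind(1, Y[ok, 1L]))))
  list(est = f$coefficients[2L], var = XtXi[2L, 2L] * rss / (n - 2))
}
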
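test_that("imputation leaves complete data untouched and preserves observed cells", {
  pop <- shared_pop()
  s <- draw_sample(pop, 400, seed = 121)

  # no missing cells: every completed dataset equals the input
  imp0 <- mvni_impute(s, mvni_config(m = 3, burn_in = 5, between = 2, seed = 1))
  for (d in imp0$datasets) expect_identical(d, s)

  sp <- calibrate_intercept(missingness_spec(1, 0.5), pop)
  inc <- apply_missingness(s, sp, seed = 122)
  imp <- mvni_impute(inc, mvni_config(m = 4, burn_in = 50, between = 20, seed = 2))
  obs <- which(!is.na(inc$distW1))
  for (d in imp$datasets) {
    expect_false(anyNA(d))
    # observed cells byte-identical across imputations and to the input
    expect_identical(d$distW1[obs], inc$distW1[obs])
    expect_identical(d[, c("diet", "race1", "race2", "grade", "health",
                           "fitness", "distW2", "ldistW2", "distW2i")],
                     inc[, c("diet", "race1", "race2", "grade", "health",
                             "fitness", "distW2", "ldistW2", "distW2i")])
    # imputed distress respects the truncation bounds and the log column
    mis <- which(is.na(inc$distW1))
    expect_true(all(d$distW1[mis] >= min(inc$distW1, na.rm = TRUE) - 1e-12))
    expect_true(all(d$distW1[mis] <= 3))
    expect_identical(d$ldistW1, log(d$distW1))
  }
  # deterministic given the seed
  imp2 <- mvni_impute(inc, mvni_config(m = 4, burn_in = 50, between = 20, seed = 2))
  expect_identical(imp$datasets, imp2$datasets)
})

test_that("the chain passes a batch-means stationarity check on a study replicate", {
  pop <- shared_pop()
  sp <- calibrate_intercept(missingness_spec(1, 0.5), pop)
  inc <- apply_missingness(draw_sample(pop, 1000, seed = 131), sp, seed = 132)
  imp <- mvni_impute(inc, mvni_config(m = 5, burn_in = 100, between = 100,
                                      seed = 3))
  tr <- imp$chain_summary$mu_trace
  post <- tr[-(1:100), , drop = FALSE]  # drop burn-in
  nb <- 10L
  bsize <- nrow(post) %/% nb
  for (j in seq_len(ncol(post))) {
    bm <- vapply(seq_len(nb), function(b) {
      mean(post[((b - 1) * bsize + 1):(b * bsize), j])
    }, numeric(1))
    half_diff <- abs(mean(bm[1:(nb / 2)]) - mean(bm[(nb / 2 + 1):nb]))
    mcse <- sd(bm) / sqrt(nb / 2)
    expect_lt(half_diff, 4 * mcse + 1e-8,
              label = paste("trace drift in", colnames(post)[j]))
  }
})

test_that("pooled slope is unbiased under MCAR on a bivariate normal toy", {
  set.seed(141)
  S <- 200
  est <- numeric(S)
  for (r in 1:S) {
    Y <- bivariate_mcar(150, rho = 0.5, miss = 0.3)
    out <- da_impute(Y, m = 5, burn_in = 50, between = 10)
    est[r] <- mean(vapply(out$datasets, function(d) slope_fit(d)$est,
                          numeric(1)))
  }
  bias <- mean(est) - 0.5
  expect_lt(abs(bias), 3 * sd(est) / sqrt(S))
})

test_that("Rubin-pooled intervals attain near-nominal coverage under MCAR", {
  set.seed(151)
  S <- 500
  cover <- logical(S)
  for (r in 1:S) {
    Y <- bivariate_mcar(120, rho = 0.5, miss = 0.3)
    out <- da_impute(Y, m = 5, burn_in = 50, between = 10)
    fits <- lapply(out$datasets, slope_fit)
    p <- rubin_pool(vapply(fits, `[[`, numeric(1), "est"),
                    vapply(fits, `[[`, numeric(1), "var"))
    cover[r] <- p$ci_low <= 0.5 && 0.5 <= p$ci_high
  }
  expect_gte(mean(cover), 0.92)
  expect_lte(mean(cover), 0.98)
})

test_that("the pooled standard error stabilises as imputations accumulate", {
  pop <- shared_pop()
  sp <- calibrate_intercept(missingness_spec(1, 0.5), pop)
  inc <- apply_missingness(draw_sample(pop, 1000, seed = 161), sp, seed = 162)
  se_m <- vapply(c(50, 100), function(m) {
    imp <- mvni_impute(inc, mvni_config(m = m, burn_in = 50, between = 10,
                                        seed = 7))
    fits <- lapply(imp$datasets, fit_linear)
    p <- rubin_pool(
      vapply(fits, function(f) f$coefficients[["ldistW1"]], numeric(1)),
      vapply(fits, function(f) f$standard_errors[["ldistW1"]]^2, numeric(1)))
    p$se
  }, numeric(1))
  expect_lt(abs(se_m[2] / se_m[1] - 1), 0.01)
})

test_that("degenerate inputs are rejected with informative errors", {
  Y <- cbind(a = c(NA, NA, NA, NA), b = c(1, 2, 3, 4))
  expect_error(da_impute(Y, m = 2), "fully missing")
  Y2 <- bivariate_mcar(50)
  expect_error(da_impute(Y2, m = 1), "at least 2")
  expect_error(mvni_config(burn_in = 0), "burn_in")
  # constant column makes the completed-data covariance singular
  Y3 <- cbind(a = rep(1, 60), b = c(rnorm(50), rep(NA, 10)))
  expect_error(da_impute(Y3, m = 2, burn_in = 5, between = 2),
               "singular|positive definite|pivot")
})
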
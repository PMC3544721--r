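test_that("linear fit interpolates noise-free data exactly", {
  set.seed(71)
  n <- 400
  d <- data.frame(diet = rbinom(n, 1, 0.3), race1 = rbinom(n, 1, 0.2),
                  race2 = rbinom(n, 1, 0.1), grade = sample(7:11, n, TRUE),
                  health = sample(1:5, n, TRUE), fitness = sample(1:5, n, TRUE),
                  ldistW1 = rnorm(n))
  b <- c(0.5, -0.2, 0.7, 0.1, -0.3, 0.05, 0.04, -0.06)
  d$ldistW2 <- b[1] + b[2] * d$diet + b[3] * d$ldistW1 + b[4] * d$race1 +
    b[5] * d$race2 + b[6] * d$grade + b[7] * d$health + b[8] * d$fitness
  f <- fit_linear(d)
  expect_equal(unname(f$coefficients), b, tolerance = 1e-10)
  expect_equal(f$n_used, n)
})

test_that("linear fit matches lm and drops incomplete records (complete-case analysis)", {
  pop <- shared_pop()
  s <- draw_sample(pop, 1500, seed = 72)
  sp <- calibrate_intercept(missingness_spec(1, 0.4), pop)
  inc <- apply_missingness(s, sp, seed = 73)
  f <- fit_linear(inc)
  ref <- lm(ldistW2 ~ diet + ldistW1 + race1 + race2 + grade + health + fitness,
            data = inc)
  expect_equal(unname(f$coefficients),
               unname(coef(ref)[names(f$coefficients)]), tolerance = 1e-10)
  expect_equal(unname(f$standard_errors),
               unname(summary(ref)$coefficients[names(f$coefficients), 2]),
               tolerance = 1e-8)
  expect_equal(f$n_used, sum(complete.cases(inc)))
})

test_that("model-based linear SEs track the sampling distribution over replicates", {
  pop <- shared_pop()
  ests <- ses <- numeric(500)
  for (r in 1:500) {
    f <- fit_linear(draw_sample(pop, 1000, seed = 1000 + r))
    ests[r] <- f$coefficients[["diet"]]
    ses[r] <- f$standard_errors[["diet"]]
  }
  expect_lt(abs(mean(ses) / sd(ests) - 1), 0.2)
})

test_that("logistic fit recovers known parameters and matches glm", {
  set.seed(81)
  n <- 4000
  d <- data.frame(diet = rbinom(n, 1, 0.3), race1 = rbinom(n, 1, 0.2),
                  race2 = rbinom(n, 1, 0.1), grade = sample(7:11, n, TRUE),
                  health = sample(1:5, n, TRUE), fitness = sample(1:5, n, TRUE),
                  ldistW1 = rnorm(n))
  eta <- -1 + 0.7 * d$diet + 1.2 * d$ldistW1 + 0.3 * d$race1 + 0.1 * d$race2 +
    0.05 * d$grade + 0.1 * d$health + 0.1 * d$fitness
  d$distW2i <- rbinom(n, 1, plogis(eta))
  f <- fit_logistic(d)
  expect_false(f$separation_flag)
  truth <- c(-1, 0.7, 1.2, 0.3, 0.1, 0.05, 0.1, 0.1)
  names(truth) <- c("(Intercept)", "diet", "ldistW1", "race1", "race2",
                    "grade", "health", "fitness")
  for (v in names(truth)) {
    expect_lt(abs(f$coefficients[[v]] - truth[[v]]),
              3 * f$standard_errors[[v]], label = v)
  }
  ref <- glm(distW2i ~ diet + ldistW1 + race1 + race2 + grade + health + fitness,
             data = d, family = binomial())
  expect_equal(unname(f$coefficients),
               unname(coef(ref)[names(f$coefficients)]), tolerance = 1e-6)
})

test_that("logistic fit flags separation when an exposure-outcome cell is empty", {
  set.seed(82)
  n <- 300
  d <- data.frame(diet = rbinom(n, 1, 0.3), race1 = rbinom(n, 1, 0.2),
                  race2 = rbinom(n, 1, 0.1), grade = sample(7:11, n, TRUE),
                  health = sample(1:5, n, TRUE), fitness = sample(1:5, n, TRUE),
                  ldistW1 = rnorm(n))
  d$distW2i <- ifelse(d$diet == 1, 1L, rbinom(n, 1, 0.3))  # empty (1, 0) cell
  f <- fit_logistic(d)
  expect_true(f$separation_flag)
})

test_that("Rubin pooling reproduces hand-computed values", {
  # m = 2, estimates {0, 1}, variances {1, 1}
  p <- rubin_pool(c(0, 1), c(1, 1))
  expect_equal(p$q_bar, 0.5)
  expect_equal(p$W, 1)
  expect_equal(p$B, 0.5)
  expect_equal(p$T, 1.75)
  expect_equal(p$df, (2 - 1) * (1 + 1 / (1.5 * 0.5))^2)  # = 49/9
  expect_equal(p$ci_low, 0.5 - qt(0.975, 49 / 9) * sqrt(1.75))

  # identical estimates: B = 0, T = W, normal quantile
  p0 <- rubin_pool(rep(0.3, 5), rep(0.04, 5))
  expect_equal(p0$B, 0)
  expect_equal(p0$T, 0.04)
  expect_identical(p0$df, Inf)
  expect_equal(p0$ci_high, 0.3 + qnorm(0.975) * 0.2)
})

test_that("pooling is permutation-invariant and never below the within variance", {
  set.seed(91)
  for (i in 1:25) {
    m <- sample(2:30, 1)
    est <- rnorm(m)
    v <- rexp(m) + 0.01
    p <- rubin_pool(est, v)
    idx <- sample(m)
    p2 <- rubin_pool(est[idx], v[idx])
    expect_equal(p$T, p2$T)
    expect_equal(p$ci_low, p2$ci_low)
    expect_gte(p$T, p$W)
    expect_gte(p$df, 0)
  }
  expect_error(rubin_pool(1, 1), "m >= 2")
  expect_error(rubin_pool(c(1, 2), c(1, -1)), "positive")
})
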
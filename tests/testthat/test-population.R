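test_that("generated population satisfies its structural invariants", {
  pop <- shared_pop()
  expect_true(all(pop$race1 * pop$race2 == 0))
  expect_identical(pop$ldistW1, log(pop$distW1))
  expect_identical(pop$distW2i, as.integer(pop$distW2 > 1))
  expect_true(all(pop$distW1 > 0 & pop$distW1 <= 3))
  expect_true(all(pop$distW2 > 0 & pop$distW2 <= 3))
  expect_true(all(pop$grade %in% 7:11))
  expect_true(all(pop$health %in% 1:5) && all(pop$fitness %in% 1:5))
  # configured marginals within Monte Carlo error at n = 2e5
  expect_lt(abs(mean(pop$diet) - 0.30), 0.005)
  expect_lt(abs(mean(pop$race1) - 0.16), 0.005)
  expect_lt(max(abs(prop.table(table(pop$grade)) - 0.2)), 0.005)
  # strong positive raw-scale skewness, residual skewness after plain log
  expect_gt(sample_skewness(pop$distW1), 1)
  expect_gt(sample_skewness(pop$ldistW1), 0.5)
  # determinism under the seed
  p2 <- generate_population(population_config(population_size = 1000, seed = 5))
  p3 <- generate_population(population_config(population_size = 1000, seed = 5))
  expect_identical(p2, p3)
})

test_that("pairwise Spearman correlations reproduce the calibration targets", {
  pop <- shared_pop()
  v <- cbind(diet = pop$diet, ldistW1 = pop$ldistW1, grade = pop$grade,
             health = pop$health, fitness = pop$fitness,
             ldistW2 = pop$ldistW2)
  S <- cor(v, method = "spearman")
  targets <- rbind(
    c("diet", "ldistW1", 0.07),   c("diet", "grade", 0.06),
    c("diet", "health", 0.07),    c("diet", "fitness", 0.13),
    c("ldistW1", "grade", 0.10),  c("ldistW1", "health", 0.22),
    c("ldistW1", "fitness", 0.22), c("grade", "health", 0.03),
    c("grade", "fitness", 0.09),  c("health", "fitness", 0.42),
    c("ldistW2", "diet", -0.0008), c("ldistW2", "ldistW1", 0.56),
    c("ldistW2", "grade", 0.07),  c("ldistW2", "health", 0.20),
    c("ldistW2", "fitness", 0.20))
  for (i in seq_len(nrow(targets))) {
    expect_lt(abs(S[targets[i, 1], targets[i, 2]] - as.numeric(targets[i, 3])),
              0.03, label = sprintf("Spearman(%s, %s) = %.3f",
                                    targets[i, 1], targets[i, 2],
                                    S[targets[i, 1], targets[i, 2]]))
  }
  # the two strongest associations are matched tightly
  expect_lt(abs(S["health", "fitness"] - 0.42), 0.02)
  expect_lt(abs(S["ldistW1", "ldistW2"] - 0.56), 0.02)
})

test_that("an identity latent correlation yields independent baseline variables", {
  cfg <- population_config(population_size = 5e4,
                           latent_correlation = diag(6), seed = 31)
  pop <- generate_population(cfg)
  v <- cbind(pop$diet, pop$ldistW1, pop$grade, pop$health, pop$fitness)
  S <- cor(v, method = "spearman")
  expect_lt(max(abs(S[upper.tri(S)])), 4 / sqrt(nrow(pop)))
})

test_that("population truth approximates the target analysis-scale coefficients", {
  tr <- fit_truth(shared_pop())
  expect_lt(abs(tr$linear$coefficients[["ldistW1"]] - 0.554), 0.05)
  expect_lt(abs(tr$linear$coefficients[["diet"]] - (-0.101)), 0.03)
  expect_true(all(is.finite(unlist(tr$logistic$coefficients))))
  expect_true(all(tr$linear$standard_errors > 0))
})

test_that("a null outcome model yields coefficients at zero within Monte Carlo error", {
  cfg <- population_config(population_size = 2e4,
                           outcome_coefs = c(alpha = 0, beta1 = 0, beta2 = 0,
                                             beta3 = 0, beta4 = 0, beta5 = 0,
                                             beta6 = 0, beta7 = 0),
                           outcome_noise_sd = 0.5, seed = 77)
  tr <- fit_truth(generate_population(cfg))
  z <- tr$linear$coefficients[-1] / tr$linear$standard_errors[-1]
  expect_true(all(abs(z) < 3))
})

test_that("standard errors of the truth fit scale as one over root n", {
  f1 <- fit_linear(generate_population(population_config(4e4, seed = 11)))
  f2 <- fit_linear(generate_population(population_config(8e4, seed = 12)))
  ratio <- f1$standard_errors[["diet"]] / f2$standard_errors[["diet"]]
  expect_lt(abs(ratio - sqrt(2)), 0.15 * sqrt(2))
})

test_that("sampling is without replacement, deterministic, and bounded by the population", {
  pop <- shared_pop()
  s <- draw_sample(pop, 1000, seed = 3)
  expect_equal(nrow(s), 1000)
  expect_false(anyNA(s))
  expect_identical(s, draw_sample(pop, 1000, seed = 3))
  expect_false(identical(s, draw_sample(pop, 1000, seed = 4)))
  expect_error(draw_sample(pop, nrow(pop) + 1), "exceeds")

  small <- generate_population(population_config(500, seed = 2))
  perm <- draw_sample(small, 500, seed = 1)
  expect_equal(sort(perm$distW1), sort(small$distW1))
})

test_that("outcome dichotomisation is strict at the threshold", {
  d <- data.frame(distW2 = c(1.0, 1.5, 0.2, 3, 1 + 1e-12))
  d <- dichotomize_outcome(d)
  expect_equal(d$distW2i, c(0L, 1L, 0L, 1L, 1L))
  low <- data.frame(distW2 = runif(50))
  expect_equal(sum(dichotomize_outcome(low)$distW2i), 0L)
})

test_that("population round-trips through CSV with missing cells as blanks", {
  pop <- shared_pop()
  s <- draw_sample(pop, 200, seed = 8)
  sp <- calibrate_intercept(missingness_spec(1, 0.25), pop)
  inc <- apply_missingness(s, sp, seed = 9)
  path <- tempfile(fileext = ".csv")
  write_population(inc, path)
  back <- read_population(path)
  expect_equal(back$distW1, inc$distW1, tolerance = 1e-12)
  expect_equal(which(is.na(back$distW1)), which(is.na(inc$distW1)))
  expect_true(file.exists(paste0(path, ".meta.json")))
  unlink(c(path, paste0(path, ".meta.json")))
})

test_that("invalid configurations are rejected with informative errors", {
  R <- diag(6); R[1, 2] <- R[2, 1] <- 1.2
  expect_error(population_config(latent_correlation = R), "positive definite")
  expect_error(population_config(race_probs = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(population_config(outcome_noise_sd = 0), "positive")
  expect_error(population_config(health_cutpoints = c(0, 0, 1, 2)),
               "increasing")
})
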
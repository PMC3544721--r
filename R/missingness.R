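#' Missing-at-random missingness specification
#'
#' Each scenario sets a single variable missing with probability given by a
#' logistic model in fully observed quantities, so the mechanism is MAR by
#' construction (the coefficient on the target variable's own value is
#' exactly zero):
#' * scenario 1 — Wave I distress missing, driven by diet, race, grade and
#'   the log Wave II outcome;
#' * scenario 2 — the dieting indicator missing, driven by race, grade, the
#'   log outcome and log Wave I distress;
#' * scenario 3 — Wave I distress missing, driven by diet, race, grade and
#'   the binary depression outcome.
#' The default log-odds coefficients are `log(2.7)` for diet, both race
#' indicators and the binary outcome, `log(1.2)` for grade, and `log(1.3)`
#' for the log-scale outcome and log baseline distress. The intercept is
#' calibrated (see [calibrate_intercept()]) so the expected missingness
#' fraction equals `target_fraction`.
#'
#' @param scenario 1, 2 or 3.
#' @param target_fraction Target missingness fraction in (0, 1); the study
#'   grid is 0.10, 0.25, 0.50, 0.75, 0.90.
#' @param coefficients Optional named log-odds vector overriding the scenario
#'   defaults; names must be model columns present in the data.
#' @param intercept Calibrated intercept (filled in by
#'   [calibrate_intercept()]).
#' @param seed Optional integer seed used when drawing the missingness
#'   indicators.
#' @return An object of class `missingness_spec`.
#' @export
missingness_spec <- function(scenario, target_fraction,
                             coefficients = NULL, intercept = NA_real_,
                             seed = NULL) {
  scenario <- as.integer(scenario)
  if (!scenario %in% 1:3) stop("scenario must be 1, 2 or 3")
  if (target_fraction <= 0 || target_fraction >= 1) {
    stop("target_fraction must be in (0, 1)")
  }
  defaults <- switch(scenario,
    `1` = list(target = "distW1",
               coef = c(diet = log(2.7), race1 = log(2.7), race2 = log(2.7),
                        grade = log(1.2), ldistW2 = log(1.3))),
    `2` = list(target = "diet",
               coef = c(race1 = log(2.7), race2 = log(2.7), grade = log(1.2),
                        ldistW2 = log(1.3), ldistW1 = log(1.3))),
    `3` = list(target = "distW1",
               coef = c(diet = log(2.7), race1 = log(2.7), race2 = log(2.7),
                        grade = log(1.2), distW2i = log(2.7))))
  coef <- if (is.null(coefficients)) defaults$coef else coefficients
  if (defaults$target %in% names(coef) && coef[[defaults$target]] != 0) {
    stop("MAR violation: coefficient on the target variable's own value ('",
         defaults$target, "') must be exactly 0")
  }
  coef <- coef[setdiff(names(coef), defaults$target)]
  out <- list(target_variable = defaults$target, scenario = scenario,
              coefficients = coef, intercept = intercept,
              target_fraction = target_fraction, seed = seed)
  class(out) <- "missingness_spec"
  out
}

#' @export
print.missingness_spec <- function(x, ...) {
  cat(sprintf("MAR scenario %d: '%s' missing, target fraction %.0f%%, intercept %s\n",
              x$scenario, x$target_variable, 100 * x$target_fraction,
              if (is.na(x$intercept)) "<uncalibrated>" else
                sprintf("%.4f", x$intercept)))
  print(round(x$coefficients, 4))
  invisible(x)
}

missingness_linpred <- function(spec, data) {
  need <- names(spec$coefficients)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missingness model columns absent: ",
                         paste(miss, collapse = ", "))
  as.numeric(as.matrix(data[, need, drop = FALSE]) %*% spec$coefficients)
}

#' Calibrate the missingness-model intercept
#'
#' Finds the intercept `c` such that the population mean of
#' `plogis(c + delta' x)` equals the target missingness fraction. The mean
#' probability is strictly increasing in `c`, so bisection on
#' `c` in `[-50, 50]` converges; iteration stops when the mean probability is
#' within `tol` of the target.
#'
#' @param spec A `missingness_spec`.
#' @param pop Population (or any large table) carrying the model covariates.
#' @param tol Tolerance on the mean probability (default `1e-8`).
#' @return A `missingness_spec` identical to `spec` but with the calibrated
#'   `intercept` filled in (use `$intercept` for the raw number).
#' @export
calibrate_intercept <- function(spec, pop, tol = 1e-8) {
  stopifnot(inherits(spec, "missingness_spec"))
  lp <- missingness_linpred(spec, pop)
  lo <- -50; hi <- 50
  mean_p <- function(c) mean(stats::plogis(c + lp))
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    pm <- mean_p(mid)
    if (abs(pm - spec$target_fraction) <= tol) break
    if (pm < spec$target_fraction) lo <- mid else hi <- mid
  }
  spec$intercept <- mid
  spec
}

#' Impose MAR missingness on a sample
#'
#' Draws an independent Bernoulli missingness indicator per record with
#' probability `plogis(intercept + delta' x)` and blanks the target variable
#' (together with its derived log column when the target is Wave I
#' distress). All other columns are untouched, and the outcome is never made
#' missing. Deterministic given `seed`.
#'
#' @param sample A complete sample.
#' @param spec A calibrated `missingness_spec`.
#' @param seed Optional seed overriding `spec$seed`.
#' @return The sample with missing cells in the target column(s) and an
#'   attribute `"miss_idx"` giving the blanked row indices.
#' @export
apply_missingness <- function(sample, spec, seed = spec$seed) {
  stopifnot(inherits(spec, "missingness_spec"))
  if (is.na(spec$intercept)) {
    stop("missingness intercept is not calibrated; run calibrate_intercept() first")
  }
  if (!spec$target_variable %in% names(sample)) {
    stop("target variable '", spec$target_variable, "' absent from the sample")
  }
  lp <- spec$intercept + missingness_linpred(spec, sample)
  if (!is.null(seed)) set.seed(seed)
  miss <- stats::runif(nrow(sample)) < stats::plogis(lp)
  out <- sample
  out[[spec$target_variable]][miss] <- NA_real_
  if (spec$target_variable == "distW1") out$ldistW1[miss] <- NA_real_
  attr(out, "miss_idx") <- which(miss)
  out
}
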
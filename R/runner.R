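#' Scenario configuration for a full simulation run
#'
#' @param scenario 1 (continuous outcome, missing Wave I distress), 2
#'   (continuous outcome, missing diet) or 3 (binary outcome, missing Wave I
#'   distress; uses the logistic analysis model).
#' @param complete_fractions Fractions of complete data to run (subset of
#'   0.90, 0.75, 0.50, 0.25, 0.10); the induced missingness fraction is one
#'   minus each value.
#' @param S Replicates per fraction (default 1000).
#' @param n Sample size per replicate (default 1000).
#' @param methods Subset of `"CCA"`, `"MVNI-log"`, `"MVNI-skew0"`.
#' @param mvni An [mvni_config()] shared by the MVNI methods.
#' @param master_seed Master seed; replicate `r` of a fraction uses a seed
#'   hashed from (master_seed, scenario, fraction, r) so any replicate is
#'   reproducible in isolation.
#' @param population A [population_config()] used when no population is
#'   passed to [run_scenario()].
#' @param output_dir Optional directory for CSV/JSON outputs.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(scenario, complete_fractions = c(0.90, 0.75, 0.50, 0.25, 0.10),
                            S = 1000L, n = 1000L,
                            methods = c("CCA", "MVNI-log", "MVNI-skew0"),
                            mvni = mvni_config(), master_seed = 1L,
                            population = population_config(),
                            output_dir = NULL) {
  scenario <- as.integer(scenario)
  if (!scenario %in% 1:3) stop("unknown scenario: must be 1, 2 or 3")
  bad <- setdiff(methods, c("CCA", "MVNI-log", "MVNI-skew0"))
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  if (any(complete_fractions <= 0 | complete_fractions >= 1)) {
    stop("complete_fractions must lie strictly in (0, 1)")
  }
  out <- list(scenario = scenario, complete_fractions = complete_fractions,
              S = as.integer(S), n = as.integer(n), methods = methods,
              mvni = mvni, master_seed = as.integer(master_seed),
              population = population, output_dir = output_dir)
  class(out) <- "scenario_config"
  out
}

#' Deterministic per-replicate seed
#'
#' Hashes (master_seed, scenario, fraction, replicate) to an integer below
#' 2^31 so each replicate of each scenario/fraction cell can be rerun in
#' isolation.
#'
#' @param master_seed,scenario,fraction,r Cell coordinates.
#' @return An integer seed.
#' @export
replicate_seed <- function(master_seed, scenario, fraction, r) {
  mod <- 2147483629
  h <- (master_seed %% mod)
  for (v in c(scenario, round(fraction * 1000), r)) {
    h <- (h * 69069 + v * 30103 + 12345) %% mod
  }
  as.integer(h)
}

# CI-augmented coefficient table from a single (complete-case) fit.
fit_ci_table <- function(fit, level = 0.95) {
  q <- if (fit$model == "linear") {
    stats::qt(1 - (1 - level) / 2, fit$n_used - length(fit$coefficients))
  } else {
    stats::qnorm(1 - (1 - level) / 2)
  }
  data.frame(coefficient = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             se = unname(fit$standard_errors),
             ci_low = unname(fit$coefficients - q * fit$standard_errors),
             ci_high = unname(fit$coefficients + q * fit$standard_errors),
             excluded = fit$separation_flag || !fit$converged)
}

run_replicate <- function(pop, specs, cfg, fraction, r) {
  seed_r <- replicate_seed(cfg$master_seed, cfg$scenario, fraction, r)
  samp <- draw_sample(pop, cfg$n, seed = seed_r)
  incomplete <- apply_missingness(samp, specs[[as.character(fraction)]])
  analysis_fit <- if (cfg$scenario == 3L) fit_logistic else fit_linear
  outcome <- if (cfg$scenario == 3L) "binary" else "continuous"
  rows <- list()
  for (method in cfg$methods) {
    tab <- if (method == "CCA") {
      f <- tryCatch(analysis_fit(incomplete), error = function(e) NULL)
      if (is.null(f)) NULL else fit_ci_table(f)
    } else {
      kind <- if (method == "MVNI-log") "log" else "log_skew0"
      imp <- mvni_impute(incomplete, cfg$mvni, transform = kind,
                         outcome = outcome)
      fits <- lapply(imp$datasets, function(d) {
        tryCatch(analysis_fit(d), error = function(e) NULL)
      })
      ok <- !vapply(fits, is.null, logical(1))
      sep <- any(vapply(fits[ok], function(f) f$separation_flag || !f$converged,
                        logical(1)))
      if (sum(ok) < 2L || sep) NULL else {
        p <- pool_fits(fits[ok])
        p$excluded <- FALSE
        p[, c("coefficient", "estimate", "se", "ci_low", "ci_high", "excluded")]
      }
    }
    if (is.null(tab)) {
      cn <- c("(Intercept)", "diet", "ldistW1", "race1", "race2", "grade",
              "health", "fitness")
      tab <- data.frame(coefficient = cn, estimate = NA_real_, se = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, excluded = TRUE)
    }
    tab$method <- method
    rows[[method]] <- tab
  }
  out <- do.call(rbind, rows)
  out$replicate <- r
  out$fraction <- fraction
  out$seed <- seed_r
  rownames(out) <- NULL
  out
}

#' Run a full simulation scenario
#'
#' Orchestrates population generation (or reuse), truth estimation,
#' missingness calibration, replicate sampling, complete-case and
#' multiply-imputed analyses, Rubin pooling and performance summaries for
#' every configured complete-data fraction and method. Replicates flagged by
#' logistic separation are excluded from summaries and counted. Byte-for-byte
#' reproducible given `master_seed`.
#'
#' @param cfg A [scenario_config()].
#' @param pop Optional pre-generated population (saves regenerating it
#'   across scenarios); generated from `cfg$population` when `NULL`.
#' @param truth Optional pre-computed [fit_truth()] result.
#' @param verbose Print per-fraction progress.
#' @return An object of class `scenario_result`: list with `long`
#'   (per-replicate coefficient table), `summaries` (per fraction x method x
#'   coefficient performance data frame), `truth`, `config`. Written as CSV
#'   plus a JSON manifest when `cfg$output_dir` is set.
#' @export
run_scenario <- function(cfg, pop = NULL, truth = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (is.null(pop)) pop <- generate_population(cfg$population)
  if (is.null(truth)) truth <- fit_truth(pop)
  truth_fit <- if (cfg$scenario == 3L) truth$logistic else truth$linear

  specs <- list()
  for (f in cfg$complete_fractions) {
    sp <- missingness_spec(cfg$scenario, target_fraction = 1 - f)
    specs[[as.character(f)]] <- calibrate_intercept(sp, pop)
  }

  long <- list()
  for (f in cfg$complete_fractions) {
    if (verbose) message(sprintf("scenario %d, %.0f%% complete: %d replicates",
                                 cfg$scenario, 100 * f, cfg$S))
    reps <- lapply(seq_len(cfg$S), function(r) run_replicate(pop, specs, cfg, f, r))
    long[[as.character(f)]] <- do.call(rbind, reps)
  }
  long <- do.call(rbind, long)
  rownames(long) <- NULL

  summaries <- summarize_scenario(long, truth_fit)
  out <- list(long = long, summaries = summaries, truth = truth, config = cfg)
  class(out) <- "scenario_result"
  if (!is.null(cfg$output_dir)) write_scenario_result(out, cfg$output_dir)
  out
}

summarize_scenario <- function(long, truth_fit) {
  cells <- unique(long[, c("fraction", "method")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    f <- cells$fraction[i]; mth <- cells$method[i]
    sub <- long[long$fraction == f & long$method == mth, ]
    for (cn in names(truth_fit$coefficients)) {
      sc <- sub[sub$coefficient == cn, ]
      df <- tryCatch({
        ps <- performance_summary(sc$estimate, sc$se, sc$ci_low, sc$ci_high,
                                  truth = truth_fit$coefficients[[cn]],
                                  excluded = sc$excluded, coefficient = cn)
        as.data.frame(ps)
      }, error = function(e) {
        # fewer than 2 usable replicates (e.g. widespread separation):
        # report the exclusion tally instead of failing the whole run
        data.frame(coefficient = cn, truth = truth_fit$coefficients[[cn]],
                   bias = NA_real_, avg_se = NA_real_, std_bias = NA_real_,
                   mse = NA_real_, coverage = NA_real_,
                   mc_error_bias = NA_real_,
                   n_replicates = sum(!sc$excluded),
                   n_excluded = sum(sc$excluded))
      })
      df$fraction <- f
      df$method <- mth
      rows[[length(rows) + 1L]] <- df
    }
  }
  out <- do.call(rbind, rows)
  out[, c("fraction", "method", "coefficient", "truth", "bias", "avg_se",
          "std_bias", "mse", "coverage", "mc_error_bias", "n_replicates",
          "n_excluded")]
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario %d: %d replicates x n = %d, fractions %s\n",
              x$config$scenario, x$config$S, x$config$n,
              paste(sprintf("%.0f%%", 100 * x$config$complete_fractions),
                    collapse = ", ")))
  rep <- x$summaries[x$summaries$coefficient %in% c("diet", "ldistW1", "health"), ]
  print(cbind(rep[, c("fraction", "method", "coefficient")],
              round(rep[, c("bias", "avg_se", "std_bias")], 3),
              coverage = sprintf("%.1f%%", 100 * rep$coverage),
              excluded = rep$n_excluded),
        row.names = FALSE)
  invisible(x)
}

#' Build the scenario report table
#'
#' Reshapes the performance summaries to the conventional report layout: one row per
#' (% complete, method), with Bias / SE / StdBias / Coverage columns for the
#' diet, distress (log Wave I) and health coefficients, ordered by
#' decreasing complete-data fraction.
#'
#' @param summaries The `summaries` data frame of a [run_scenario()] result
#'   (or a `scenario_result`).
#' @param path Optional CSV path to write.
#' @param coefficients Coefficients reported as blocks.
#' @return The wide report data frame (invisibly written to `path` if given).
#' @export
make_report <- function(summaries, path = NULL,
                        coefficients = c("diet", "ldistW1", "health")) {
  if (inherits(summaries, "scenario_result")) summaries <- summaries$summaries
  if (!nrow(summaries)) {
    wide <- data.frame(pct_complete = numeric(), method = character())
  } else {
    cells <- unique(summaries[, c("fraction", "method")])
    cells <- cells[order(-cells$fraction, cells$method), ]
    rows <- lapply(seq_len(nrow(cells)), function(i) {
      sub <- summaries[summaries$fraction == cells$fraction[i] &
                         summaries$method == cells$method[i], ]
      row <- data.frame(pct_complete = 100 * cells$fraction[i],
                        method = cells$method[i])
      for (cn in coefficients) {
        s <- sub[sub$coefficient == cn, ]
        row[[paste0(cn, "_bias")]] <- s$bias
        row[[paste0(cn, "_se")]] <- s$avg_se
        row[[paste0(cn, "_stdbias")]] <- s$std_bias
        row[[paste0(cn, "_coverage")]] <- s$coverage
      }
      row$n_excluded <- max(sub$n_excluded)
      row
    })
    wide <- do.call(rbind, rows)
  }
  if (!is.null(path)) utils::write.csv(wide, path, row.names = FALSE)
  invisible(wide)
}

write_scenario_result <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(res$long, file.path(dir, sprintf("scenario%d_long.csv",
                                                    res$config$scenario)),
                   row.names = FALSE)
  utils::write.csv(res$summaries,
                   file.path(dir, sprintf("scenario%d_summary.csv",
                                          res$config$scenario)),
                   row.names = FALSE)
  make_report(res$summaries,
              file.path(dir, sprintf("scenario%d_report.csv",
                                     res$config$scenario)))
  manifest <- list(scenario = res$config$scenario, S = res$config$S,
                   n = res$config$n, methods = res$config$methods,
                   master_seed = res$config$master_seed,
                   complete_fractions = res$config$complete_fractions,
                   mvni = res$config$mvni[c("m", "burn_in", "between", "init")])
  jsonlite::write_json(manifest, file.path(dir, sprintf("scenario%d_manifest.json",
                                                        res$config$scenario)),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Plot performance against the complete-data fraction
#'
#' Simple base-graphics hook: mean squared error (or another summary column)
#' of one coefficient against the percentage of complete data, one line per
#' method.
#'
#' @param x A `scenario_result`.
#' @param coefficient Coefficient to display (default `"diet"`).
#' @param measure Summary column to plot (default `"mse"`).
#' @param ... Passed to [graphics::matplot()].
#' @return The plotted wide matrix, invisibly.
#' @export
plot.scenario_result <- function(x, coefficient = "diet", measure = "mse", ...) {
  s <- x$summaries[x$summaries$coefficient == coefficient, ]
  fr <- sort(unique(s$fraction), decreasing = TRUE)
  methods <- unique(s$method)
  m <- sapply(methods, function(mt) {
    s[[measure]][match(paste(fr, mt), paste(s$fraction, s$method))]
  })
  m <- matrix(m, nrow = length(fr), dimnames = list(100 * fr, methods))
  graphics::matplot(100 * fr, m, type = "b", pch = seq_along(methods),
                    lty = 1, xlim = rev(range(100 * fr)),
                    xlab = "% complete data",
                    ylab = paste(measure, "for", coefficient), ...)
  graphics::legend("topleft", legend = methods, pch = seq_along(methods),
                   col = seq_along(methods), lty = 1, bty = "n")
  invisible(m)
}
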
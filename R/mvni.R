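#' Configuration of the multivariate normal imputation engine
#'
#' @param m Number of imputations (default 20).
#' @param burn_in MCMC iterations discarded before the first retained draw
#'   (default 200).
#' @param between Iterations between retained draws (default 100).
#' @param prior Only `"uniform"` is implemented: the posterior is
#'   inverse-Wishart with `n - 1` degrees of freedom for the covariance and
#'   normal for the mean.
#' @param seed Optional integer seed.
#' @param init Chain initialisation: `"em"` (EM to the maximum-likelihood
#'   moments, the default) or `"moments"` (mean-filled sample moments).
#' @param round_binary Round imputed values of binary 0/1 columns at 0.5.
#'   Off by default: imputed binary covariates are left continuous when used
#'   in the analysis model.
#' @return An object of class `mvni_config`.
#' @export
mvni_config <- function(m = 20L, burn_in = 200L, between = 100L,
                        prior = "uniform", seed = NULL, init = c("em", "moments"),
                        round_binary = FALSE) {
  init <- match.arg(init)
  if (m < 2L) stop("m must be at least 2")
  if (burn_in < 1L || between < 1L) stop("burn_in and between must be >= 1")
  if (!identical(prior, "uniform")) stop("only the uniform prior is implemented")
  out <- list(m = as.integer(m), burn_in = as.integer(burn_in),
              between = as.integer(between), prior = prior, seed = seed,
              init = init, round_binary = isTRUE(round_binary))
  class(out) <- "mvni_config"
  out
}

#' Low-level multivariate normal data-augmentation imputation
#'
#' Runs the I-step / P-step Markov chain on a plain numeric matrix with
#' `NA` marking the missing cells and returns `m` completed matrices on the
#' same (working) scale, plus the chain's mean-vector trace. Observed cells
#' are returned byte-identical to the input. Deterministic given `seed`.
#'
#' @param Y Numeric matrix with `NA` for missing cells; no column may be
#'   fully missing and `nrow(Y)` must exceed `ncol(Y) + 1`.
#' @param m,burn_in,between,init See [mvni_config()].
#' @param seed Optional seed.
#' @param em_maxit,em_tol EM initialisation controls.
#' @return List with `datasets` (length-`m` list of completed matrices),
#'   `mu_trace` (iterations x columns matrix of posterior mean draws, `NULL`
#'   when there is nothing to impute) and `n_patterns`.
#' @export
da_impute <- function(Y, m = 20L, burn_in = 200L, between = 100L,
                      seed = NULL, init = "em", em_maxit = 100L,
                      em_tol = 1e-6) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (!is.null(seed)) set.seed(seed)
  n_obs <- colSums(!is.na(Y))
  if (any(n_obs == 0L)) {
    stop("column(s) fully missing: ",
         paste(colnames(Y)[n_obs == 0L], collapse = ", "))
  }
  if (!anyNA(Y)) {
    return(list(datasets = rep(list(Y), m), mu_trace = NULL, n_patterns = 0L))
  }
  init <- if (init == "complete_case_moments") "moments" else init
  out <- .da_impute_cpp(Y, as.integer(m), as.integer(burn_in),
                        as.integer(between), init, as.integer(em_maxit),
                        em_tol)
  out$datasets <- lapply(out$datasets, function(d) {
    dimnames(d) <- dimnames(Y)
    d
  })
  colnames(out$mu_trace) <- colnames(Y)
  out
}

# Variables entering the imputation model and their transform targets.
mvni_model_columns <- function(outcome) {
  c("diet", "race1", "race2", "grade", "health", "fitness", "distW1",
    if (outcome == "binary") "distW2i" else "distW2")
}

#' Multivariate normal imputation of an incomplete sample
#'
#' Builds the joint imputation model over diet, the race indicators, grade
#' (as a linear predictor), the health and fitness scores, Wave I distress
#' and the analysis outcome (log Wave II distress, or the binary depression
#' indicator for the dichotomised analysis). The skewed variables (distress
#' at both waves, health and fitness) enter on a transformed scale — simple
#' log, or the zero-skewness shifted log — with transforms fitted on the
#' observed values only and shared by all `m` imputations. Missing cells are
#' drawn by data-augmentation MCMC under the uniform prior, back-transformed
#' to the original scale, and truncated: values above the scale maximum are
#' set to the maximum (both transforms), values below the smallest observed
#' value are raised to it (zero-skewness transform).
#'
#' @param incomplete A sample with missing cells (as produced by
#'   [apply_missingness()]).
#' @param cfg An [mvni_config()].
#' @param transform `"log"` or `"log_skew0"` (controls the transform fitted
#'   to every skewed variable).
#' @param outcome `"continuous"` (log Wave II distress in the imputation
#'   model) or `"binary"` (depression indicator, used with the logistic
#'   analysis model).
#' @return An object of class `mvni_result`: list with `datasets`
#'   (length-`m` list of completed data frames on the original scale),
#'   `chain_summary`, `transforms`, `config`, `transform`, `outcome`.
#' @export
mvni_impute <- function(incomplete, cfg = mvni_config(),
                        transform = c("log_skew0", "log"),
                        outcome = c("continuous", "binary")) {
  transform <- match.arg(transform)
  outcome <- match.arg(outcome)
  stopifnot(inherits(cfg, "mvni_config"))
  cols <- mvni_model_columns(outcome)
  miss <- setdiff(cols, names(incomplete))
  if (length(miss)) stop("imputation model columns absent: ",
                         paste(miss, collapse = ", "))

  skewed <- intersect(c("health", "fitness", "distW1", "distW2"), cols)
  scale_max <- c(health = 5, fitness = 5, distW1 = 3, distW2 = 3)
  transforms <- lapply(skewed, function(v) {
    fit_transform(incomplete[[v]], kind = transform, var = v,
                  scale_max = scale_max[[v]])
  })
  names(transforms) <- skewed

  W <- sapply(cols, function(v) {
    if (v %in% skewed) apply_transform(incomplete[[v]], transforms[[v]])
    else as.numeric(incomplete[[v]])
  })
  colnames(W) <- cols

  raw <- da_impute(W, m = cfg$m, burn_in = cfg$burn_in,
                   between = cfg$between, seed = cfg$seed, init = cfg$init)

  na_cols <- cols[colSums(is.na(W)) > 0L]
  datasets <- lapply(raw$datasets, function(d) {
    comp <- incomplete
    for (v in na_cols) {
      idx <- which(is.na(incomplete[[v]]))
      if (v %in% skewed) {
        vals <- invert_transform(d[idx, v], transforms[[v]])
        vals <- truncate_imputed(vals, transforms[[v]])
      } else {
        vals <- d[idx, v]
        if (cfg$round_binary && all(incomplete[[v]] %in% c(0, 1, NA))) {
          vals <- as.numeric(vals > 0.5)
        }
      }
      comp[[v]][idx] <- vals
      if (v == "distW1") comp$ldistW1[idx] <- log(comp$distW1[idx])
      if (v == "distW2") {
        comp$ldistW2[idx] <- log(comp$distW2[idx])
        comp$distW2i[idx] <- as.integer(comp$distW2[idx] > 1)
      }
    }
    comp
  })

  chain_summary <- NULL
  if (!is.null(raw$mu_trace)) {
    tr <- raw$mu_trace
    h <- nrow(tr) %/% 2L
    chain_summary <- list(mu_trace = tr,
                          mean_first_half = colMeans(tr[seq_len(h), , drop = FALSE]),
                          mean_second_half = colMeans(tr[(h + 1L):nrow(tr), , drop = FALSE]))
  }
  out <- list(datasets = datasets, chain_summary = chain_summary,
              transforms = transforms, config = cfg, transform = transform,
              outcome = outcome, n_missing = sum(is.na(W)))
  class(out) <- "mvni_result"
  out
}

#' @export
print.mvni_result <- function(x, ...) {
  cat(sprintf("MVNI result: %d imputations of %d missing cells (%s transform, %s outcome)\n",
              length(x$datasets), x$n_missing, x$transform, x$outcome))
  invisible(x)
}

#' @export
summary.mvni_result <- function(object, ...) {
  cat(sprintf("MVNI: m = %d, burn-in %d, between %d, init '%s'\n",
              object$config$m, object$config$burn_in, object$config$between,
              object$config$init))
  for (t in object$transforms) print(t)
  if (!is.null(object$chain_summary)) {
    cat("Posterior-mean trace (first vs second half):\n")
    print(round(rbind(first = object$chain_summary$mean_first_half,
                      second = object$chain_summary$mean_second_half), 4))
  }
  invisible(object)
}
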
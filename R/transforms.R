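#' Moment coefficient of skewness
#'
#' Sample skewness `g1 = m3 / m2^(3/2)` with biased (moment) central moments
#' `mk = mean((x - mean(x))^k)`. Scale-free; used as the criterion for the
#' zero-skewness shifted log transformation.
#'
#' @param x Numeric vector, length >= 3, not all equal.
#' @return The skewness coefficient (a single number).
#' @export
sample_skewness <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L) stop("need at least 3 observations to compute skewness")
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 <= 0) stop("skewness undefined: all values equal")
  mean(xc^3) / m2^1.5
}

#' Zero-skewness shifted log transformation
#'
#' Finds the sign `s` and shift `k` such that `u = ln(s*x - k)` has sample
#' skewness zero (within `tol`). `s = +1` for right-skewed input, `-1` for
#' left-skewed. The skewness of `ln(s*x - k)` is strictly decreasing in `k`
#' on `(-Inf, min(s*x))`, from the skewness of `s*x` down to `-Inf`, so the
#' root is found by bracketing.
#'
#' @param x Numeric vector (length >= 3, not all equal).
#' @param tol Tolerance on the post-transform skewness (default `1e-6`;
#'   the fitted transform is required to be within `1e-4` in any case).
#' @return A list with elements `sign`, `shift_k`, `skewness` (residual
#'   skewness of the transformed values) and `boundary` (`TRUE` when the
#'   search hit its bracket bound on near-symmetric input and the returned
#'   shift is the boundary value).
#' @export
zero_skew_shift <- function(x, tol = 1e-6) {
  x <- as.numeric(x)
  if (length(x) < 3L) stop("need at least 3 observations")
  g0 <- sample_skewness(x)
  s <- if (g0 >= 0) 1 else -1
  y <- s * x
  ymin <- min(y)
  rng <- max(y) - ymin
  if (rng <= 0) stop("all values equal: shift is undefined")

  skew_at <- function(k) sample_skewness(log(y - k))

  # upper bound: just below min(y) the log of the smallest value diverges to
  # -Inf and the skewness is strongly negative
  hi <- ymin - 1e-9 * rng
  # expand the lower bound until the skewness is positive (or give up: the
  # input is effectively symmetric after any admissible shift)
  lo <- ymin - rng
  expand <- 0L
  while (skew_at(lo) < 0 && expand < 60L) {
    lo <- ymin - rng * 2^(expand + 1L)
    expand <- expand + 1L
  }
  if (skew_at(lo) < 0) {
    warning("input is near-symmetric: returning boundary shift")
    return(list(sign = s, shift_k = lo, skewness = skew_at(lo),
                boundary = TRUE))
  }
  if (skew_at(hi) > 0) {
    # pathological: even an extreme left tail cannot pull skewness below 0
    warning("skewness positive at search bound: returning boundary shift")
    return(list(sign = s, shift_k = hi, skewness = skew_at(hi),
                boundary = TRUE))
  }
  root <- stats::uniroot(skew_at, lower = lo, upper = hi,
                         tol = .Machine$double.eps^0.6, maxiter = 2000L)
  k <- root$root
  g <- skew_at(k)
  # polish with bisection if uniroot's x-tolerance left residual skewness
  if (abs(g) > tol) {
    lo2 <- lo; hi2 <- hi
    for (i in seq_len(200L)) {
      mid <- (lo2 + hi2) / 2
      gm <- skew_at(mid)
      if (abs(gm) <= tol) { k <- mid; g <- gm; break }
      if (gm > 0) lo2 <- mid else hi2 <- mid
      k <- mid; g <- gm
    }
  }
  list(sign = s, shift_k = k, skewness = g, boundary = FALSE)
}

#' Fit a normalising transformation for a skewed variable
#'
#' Builds a `skew_transform` object of kind `"log"` (`u = ln(x)`) or
#' `"log_skew0"` (`u = ln(s*x - k)` with `k`, `s` chosen so that the
#' transformed observed values have zero skewness). The transform is fitted
#' on observed values only and records the per-sample smallest observed value
#' and the scale maximum, which drive the truncation of back-transformed
#' imputed values.
#'
#' @param x Observed values (missing entries allowed; they are ignored).
#' @param kind `"log"` or `"log_skew0"`.
#' @param var Variable name carried along for reporting.
#' @param scale_max Upper bound of the measurement scale (3 for the distress
#'   score, 5 for the health and fitness scores).
#' @return An object of class `skew_transform` with fields `kind`, `sign`,
#'   `shift_k`, `fitted_on` (name and number of observed values used),
#'   `scale_max`, `observed_min`, `boundary`.
#' @export
fit_transform <- function(x, kind = c("log", "log_skew0"), var = "x",
                          scale_max = Inf) {
  kind <- match.arg(kind)
  obs <- as.numeric(x[!is.na(x)])
  if (length(obs) < 3L) stop("need at least 3 observed values to fit a transform")
  if (kind == "log") {
    if (any(obs <= 0)) stop("log transform requires positive values in '", var, "'")
    t <- list(kind = "log", sign = 1, shift_k = 0,
              fitted_on = list(var = var, n = length(obs)),
              scale_max = scale_max, observed_min = min(obs), boundary = FALSE)
  } else {
    z <- zero_skew_shift(obs)
    t <- list(kind = "log_skew0", sign = z$sign, shift_k = z$shift_k,
              fitted_on = list(var = var, n = length(obs)),
              scale_max = scale_max, observed_min = min(obs),
              boundary = z$boundary)
  }
  class(t) <- "skew_transform"
  t
}

#' @export
print.skew_transform <- function(x, ...) {
  cat(sprintf("skew_transform '%s' on '%s' (n = %d): u = ln(%sx - %.6g)\n",
              x$kind, x$fitted_on$var, x$fitted_on$n,
              if (x$sign >= 0) "" else "-", x$shift_k))
  invisible(x)
}

#' Apply / invert a fitted transformation
#'
#' `apply_transform` maps `x` to `u = ln(s*x - k)`; `invert_transform` maps
#' `u` back to `x = s*(exp(u) + k)`. The two are mutually inverse.
#'
#' @param x,u Numeric vectors (missing values pass through).
#' @param t A `skew_transform`.
#' @return Transformed numeric vector.
#' @export
apply_transform <- function(x, t) {
  stopifnot(inherits(t, "skew_transform"))
  arg <- t$sign * x - t$shift_k
  bad <- which(!is.na(arg) & arg <= 0)
  if (length(bad)) {
    stop(sprintf("transform domain violation in '%s': value %.6g gives %s*x - k = %.6g <= 0",
                 t$fitted_on$var, x[bad[1L]], if (t$sign >= 0) "+1" else "-1",
                 arg[bad[1L]]))
  }
  log(arg)
}

#' @rdname apply_transform
#' @export
invert_transform <- function(u, t) {
  stopifnot(inherits(t, "skew_transform"))
  t$sign * (exp(u) + t$shift_k)
}

#' Truncate back-transformed imputed values to the measurement scale
#'
#' Imputed values above the scale maximum are set to the scale maximum (both
#' transform kinds); for the zero-skewness transform, imputed values below
#' the smallest observed value in the sample are raised to that minimum.
#' Only positions flagged as imputed are modified.
#'
#' @param values Numeric vector on the original scale.
#' @param t The `skew_transform` the values were imputed under.
#' @param imputed Logical vector marking imputed cells (default: all).
#' @return The truncated vector; idempotent.
#' @export
truncate_imputed <- function(values, t, imputed = rep(TRUE, length(values))) {
  stopifnot(inherits(t, "skew_transform"), length(imputed) == length(values))
  v <- values
  idx <- which(imputed)
  if (!length(idx)) return(v)
  if (t$kind == "log_skew0") {
    v[idx] <- pmax(v[idx], t$observed_min)
  }
  if (is.finite(t$scale_max)) {
    v[idx] <- pmin(v[idx], t$scale_max)
  }
  v
}
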
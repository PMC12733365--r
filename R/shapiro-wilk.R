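#' Generalized Shapiro-Wilk W statistic
#'
#' `W = (sum_i a_{n-i+1} (x_{n-i+1} - x_i))^2 / sum_i (x_i - mean(x))^2`
#' over the ascending-sorted sample, with the small-sample coefficients of
#' [sw_coefficients()]. W lies in (0, 1]; the closer to 1, the more the
#' sorted sample resembles normal order statistics. W is invariant under
#' affine rescaling of the sample.
#'
#' @param x numeric sample (sorted internally), 3 to 50 values, not all
#'   equal.
#' @return W, with the coefficient source as attribute `"source"`.
#' @examples
#' sw_w(c(1, 2, 3))   # exactly 1: a perfectly linear sorted triple
#' @export
sw_w <- function(x) {
  n <- length(x)
  if (n < 3) stop("W needs at least 3 values")
  x <- sort(x)
  den <- sum((x - mean(x))^2)
  if (den == 0) stop("W undefined for a constant sample")
  a <- sw_coefficients(n)
  m <- length(a)
  w <- sum(a * (x[n:(n - m + 1)] - x[seq_len(m)]))^2 / den
  structure(min(w, 1), source = attr(a, "source"))
}

#' Royston's p-value transformation for W
#'
#' Maps `g = ln(1 - W)` to a standard normal deviate with the 12-2000
#' moment approximations
#' `mu_z = 0.0038915 ln(n)^3 - 0.083751 ln(n)^2 - 0.31082 ln(n) - 1.5861`
#' and
#' `sigma_z = exp(0.0030302 ln(n)^2 - 0.082676 ln(n) - 0.4803)`;
#' the p-value is `1 - pnorm((g - mu_z)/sigma_z)`. These constants are
#' applied for every `n >= 3`: the published alternative constants for
#' n of 4-11 collapse to p = 0 on intervalized count samples and are not
#' usable, while the 12-2000 curves extrapolate smoothly.
#'
#' @param w W statistic in (0, 1].
#' @param n effective sample size (number of values W was computed from).
#' @return p-value in (0, 1).
#' @export
royston_p <- function(w, n) {
  if (any(w <= 0 | w > 1)) stop("W must lie in (0, 1]")
  if (n < 3) stop("n must be at least 3")
  ln <- log(n)
  mu_z <- 0.0038915 * ln^3 - 0.083751 * ln^2 - 0.31082 * ln - 1.5861
  sigma_z <- exp(0.0030302 * ln^2 - 0.082676 * ln - 0.4803)
  stats::pnorm((log1p(-w) - mu_z) / sigma_z, lower.tail = FALSE)
}

new_sw_result <- function(w, p, alpha, method, n, source = NULL) {
  structure(list(w = as.numeric(w), p = p,
                 verdict = if (p >= alpha) "normal" else "not-normal",
                 alpha = alpha, method = method, n = n,
                 coefficient_source = source),
            class = "sw_result")
}

#' @export
print.sw_result <- function(x, ...) {
  cat(sprintf("Shapiro-Wilk (%s): W = %.4f, p = %.4g, n = %d -> %s (alpha = %g)\n",
              x$method, x$w, x$p, x$n, x$verdict, x$alpha))
  invisible(x)
}

#' Hybrid Shapiro-Wilk normality test on an intervalized series
#'
#' The workhorse normality test for lifespan frequency series: the
#' generalized W statistic with the original small-sample coefficients,
#' computed on the *ascending-sorted per-interval death counts* (so the
#' effective sample size is the number of intervals, not the cohort size),
#' combined with Royston's p-value transformation, which removes the
#' 50-value ceiling of the original percentage-point tables. The verdict is
#' "normal" when `p >= alpha`.
#'
#' The series must already be free of leading/trailing zero intervals; pass
#' it through [trim_zero_intervals()] first (empty edge bins change the
#' coefficient set and distort W and p). Display-only padded series are
#' refused. Series produced by [equalize_pair()] are exempt from the edge
#' check: an interval empty in only one sample of a pair is deliberately
#' kept to hold the interval counts equal.
#'
#' @param f a `frequency_series` with 3 to 50 intervals.
#' @param alpha significance level for the verdict (default 0.05).
#' @param warn_small warn when the interval count is below 12, the lower end
#'   of the p-transformation's published validity range.
#' @return an `sw_result` with fields `w`, `p`, `verdict`, `method`, `n`
#'   (number of intervals) and `coefficient_source`.
#' @export
sw_test_hybrid <- function(f, alpha = 0.05, warn_small = TRUE) {
  stopifnot(inherits(f, "frequency_series"))
  if (isTRUE(f$display_only))
    stop("refusing a display-only (zero-padded) series; test the trimmed series")
  if (!isTRUE(f$equalized) && f$k > 1 &&
      (f$counts[1L] == 0L || f$counts[f$k] == 0L))
    stop("leading/trailing zero intervals present; apply trim_zero_intervals() first")
  if (f$k < 3) stop("need at least 3 intervals")
  if (f$k > 50) stop("more than 50 intervals; use sw_test_royston() on the raw series")
  if (warn_small && f$k < 12)
    warning("interval count ", f$k, " is below 12; Royston's p transformation is extrapolated")
  w <- sw_w(f$counts)
  new_sw_result(w, royston_p(as.numeric(w), f$k), alpha, "hybrid", f$k,
                attr(w, "source"))
}

#' Full Royston Shapiro-Wilk test on a raw lifespan series
#'
#' W computed with Royston's polynomial-approximated weights and the p-value
#' of [royston_p()], applied to the individual lifespans (not intervalized).
#' Suitable for the large samples typical of survival assays; supported for
#' n of 12 to 5000.
#'
#' @param s a `lifespan_series` (or `deaths_per_day`).
#' @param alpha significance level.
#' @return an `sw_result` with `n` equal to the cohort size.
#' @export
sw_test_royston <- function(s, alpha = 0.05) {
  x <- sort(as.numeric(as_lifespans(s)))
  n <- length(x)
  if (n < 12 || n > 5000) stop("Royston's method is supported for n between 12 and 5000")
  den <- sum((x - mean(x))^2)
  if (den == 0) stop("W undefined for a constant sample")
  a <- .royston_weights(n)
  w <- min(sum(a * x)^2 / den, 1)
  new_sw_result(w, royston_p(w, n), alpha, "royston-full", n)
}
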
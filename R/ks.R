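#' Normal cumulative distribution function
#'
#' `F(x) = (1 + erf((x - mu)/(sigma sqrt(2)))) / 2`, the reference CDF of
#' the one-sample normality test.
#'
#' @param x evaluation points (days).
#' @param mu,sigma mean and standard deviation of the reference normal
#'   (`sigma > 0`).
#' @return probabilities.
#' @export
normal_cdf <- function(x, mu, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  stats::pnorm(x, mu, sigma)
}

#' Empirical cumulative distribution function
#'
#' Right-continuous step function with value rank/N at each order
#' statistic; tied values collapse to the highest rank.
#'
#' @param x numeric sample.
#' @return a function of one argument returning ECDF values.
#' @export
empirical_cdf <- function(x) {
  n <- length(x)
  if (n < 1) stop("empty sample")
  sx <- sort(x)
  function(q) vapply(q, function(qi) sum(sx <= qi) / n, numeric(1))
}

## Supremum gap between the ECDF of x and Normal(mu, sigma): evaluated at
## each distinct data value (ECDF above the reference) and immediately
## before it (reference above the ECDF). Returns D and the signed deviation
## at the supremum (positive = experimental CDF above/left of expected).
.ks_sup <- function(x, mu, sigma) {
  n <- length(x)
  ux <- sort(unique(x))
  ec_hi <- vapply(ux, function(v) sum(x <= v), numeric(1)) / n
  ec_lo <- vapply(ux, function(v) sum(x < v), numeric(1)) / n
  ref <- stats::pnorm(ux, mu, sigma)
  dev <- c(ec_hi - ref, ec_lo - ref)
  i <- which.max(abs(dev))
  list(d = abs(dev[i]), signed = dev[i])
}

new_ks1_result <- function(d, signed, p, d_crit, alpha, method, n) {
  verdict <- if (!is.na(d_crit)) {
    if (d < d_crit) "normal" else "not-normal"
  } else if (p > alpha) "normal" else "not-normal"
  structure(list(d = d, d_signed = signed, p = p, d_crit = d_crit,
                 verdict = verdict, method = method, n = n, alpha = alpha),
            class = "ks1_result")
}

#' @export
print.ks1_result <- function(x, ...) {
  cat(sprintf("One-sample KS (%s): D = %.4f (signed %+.4f), p = %.4g, D_crit = %s, n = %d -> %s\n",
              x$method, x$d, x$d_signed, x$p,
              if (is.na(x$d_crit)) "-" else sprintf("%.4f", x$d_crit),
              x$n, x$verdict))
  invisible(x)
}

#' One-sample Kolmogorov-Smirnov normality test
#'
#' Tests a sample against the normal distribution with mean and SD
#' estimated from the same sample. The statistic is the supremum of the
#' absolute gap between the empirical CDF (rank/N steps) and the fitted
#' normal CDF, scanned at every distinct value and immediately before it;
#' the signed deviation at the supremum is reported (positive when the
#' empirical CDF lies above, i.e. deviates leftward).
#'
#' For a raw `lifespan_series` the sample is the individual lifespans
#' (effective n = cohort size). For an intervalized `frequency_series` the
#' sample is the per-interval death counts - the same convention as the
#' hybrid SW test - so the effective n is the number of intervals; the
#' series must be trimmed of empty edge intervals first.
#'
#' The verdict is "normal" when D is below the critical value at `alpha`
#' (plain table, or the stricter Lilliefors-corrected table with
#' `method = "lilliefors"`); where no critical value is tabled the p-value
#' is compared to `alpha` instead. p-values come from Kolmogorov's series
#' (default) or Marsaglia's approximation (`method = "marsaglia"`, for
#' n >= 100).
#'
#' @param x a `lifespan_series`, `deaths_per_day` or trimmed
#'   `frequency_series`.
#' @param alpha significance level.
#' @param method `"kolmogorov"`, `"marsaglia"` or `"lilliefors"`.
#' @return a `ks1_result` with `d`, `d_signed`, `p`, `d_crit`, `verdict`,
#'   `method`, `n`.
#' @export
ks_one_sample <- function(x, alpha = 0.05,
                          method = c("kolmogorov", "marsaglia", "lilliefors")) {
  method <- match.arg(method)
  if (inherits(x, "frequency_series")) {
    if (isTRUE(x$display_only))
      stop("refusing a display-only (zero-padded) series; test the trimmed series")
    if (!isTRUE(x$equalized) && x$k > 1 &&
        (x$counts[1L] == 0L || x$counts[x$k] == 0L))
      stop("leading/trailing zero intervals present; apply trim_zero_intervals() first")
    smp <- as.numeric(x$counts)
  } else {
    smp <- as.numeric(as_lifespans(x))
  }
  n <- length(smp)
  if (n < 3) stop("need at least 3 values")
  mu <- mean(smp); sigma <- stats::sd(smp)
  if (sigma == 0) stop("zero variance: KS statistic undefined")
  sup <- .ks_sup(smp, mu, sigma)
  p <- switch(method,
              kolmogorov = kolmogorov_pvalue(sup$d, n),
              marsaglia = marsaglia_pvalue(sup$d, n, cap = TRUE),
              lilliefors = kolmogorov_pvalue(sup$d, n))
  d_crit <- tryCatch(
    ks_critical_value(n, alpha,
                      corrected = if (method == "lilliefors") "lilliefors" else "plain"),
    error = function(e) NA_real_)
  new_ks1_result(sup$d, sup$signed, p, d_crit, alpha, method, n)
}

#' Product-limit survival curve
#'
#' `S_t = prod_{i <= t} (n_i - d_i)/n_i`, the fraction of the cohort
#' surviving through day t. With full follow-up (no censoring, as in a
#' lifespan assay run to 100% mortality) this equals
#' `(N - cumulative deaths through t)/N`, and the curve reaches 0 on the
#' last mortality day.
#'
#' @param s a `lifespan_series` or `deaths_per_day` object.
#' @return a `survival_curve`: list with `day` (0..T), `s` (survival
#'   probabilities) and `n`.
#' @export
survival_curve <- function(s) {
  d <- as_deaths(s)
  at_risk <- d$n - c(0, cumsum(d$counts))[seq_along(d$counts)]
  surv <- cumprod((at_risk - d$counts) / at_risk)
  structure(list(day = seq_along(d$counts) - 1L, s = surv, n = d$n),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("Product-limit survival curve: n =", x$n, ", reaches",
      signif(min(x$s), 3), "on day", max(x$day), "\n")
  invisible(x)
}

new_ks2_result <- function(d, d_crit, z, p, alpha, sided, n, m) {
  structure(list(d = d, d_crit = d_crit, z = z, p = p,
                 verdict = if (d > d_crit) "different" else "not-different",
                 sided = sided, alpha = alpha, n = n, m = m),
            class = "ks2_result")
}

#' @export
print.ks2_result <- function(x, ...) {
  cat(sprintf("Two-sample KS (%s-sided): D = %.4f, D_crit = %.4f, z = %.3f, p = %.4g -> %s\n",
              x$sided, x$d, x$d_crit, x$z, x$p, x$verdict))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test on survival curves
#'
#' Compares two fully observed cohorts through the supremum gap between
#' their product-limit survival curves over all days,
#' `D = sup_t |S_1(t) - S_2(t)|`. The critical value is
#' `d_alpha(alpha) * sqrt((n + m)/(n m))` and the p-value comes from
#' Kolmogorov's series at `z = D * sqrt(n m/(n + m))`. One-sided p-values
#' use the refined approximation
#' `P = exp(-2 z^2 - (2 z/3) (m + 2 n)/sqrt(m n (m + n)))`
#' (`one_sided_rule = "refined"`) or simply half the two-sided value
#' (`"half"`).
#'
#' @param a,b `lifespan_series` or `deaths_per_day` cohorts.
#' @param alpha significance level.
#' @param sided `"two"` or `"one"`.
#' @param one_sided_rule approximation used when `sided = "one"`.
#' @return a `ks2_result` with `d`, `d_crit`, `z`, `p`, `verdict`.
#' @examples
#' a <- lifespan_series(rep(c(10, 20, 30), 20))
#' ks_two_sample(a, a)$d    # identical cohorts: D = 0
#' @export
ks_two_sample <- function(a, b, alpha = 0.05, sided = c("two", "one"),
                          one_sided_rule = c("refined", "half")) {
  sided <- match.arg(sided); one_sided_rule <- match.arg(one_sided_rule)
  sa <- survival_curve(a); sb <- survival_curve(b)
  n <- sa$n; m <- sb$n
  tmax <- max(max(sa$day), max(sb$day))
  pad <- function(sc) c(sc$s, rep(0, tmax - max(sc$day)))
  d <- max(abs(pad(sa) - pad(sb)))
  z <- d * sqrt(n * m / (n + m))
  d_crit <- d_alpha(alpha) * sqrt((n + m) / (n * m))
  p <- if (sided == "two") {
    kolmogorov_pvalue(z, 1)
  } else if (one_sided_rule == "half") {
    kolmogorov_pvalue(z, 1) / 2
  } else {
    min(exp(-2 * z^2 - (2 * z / 3) * (m + 2 * n) / sqrt(m * n * (m + n))), 1)
  }
  new_ks2_result(d, d_crit, z, p, alpha, sided, n, m)
}
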
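## Exact critical values of the one-sample Kolmogorov-Smirnov statistic,
## n = 1..34 (the classic Smirnov/Massey percentage points, frozen here to
## five decimals from the exact null distribution of D_n). For n >= 35 the
## asymptotic d_alpha/sqrt(n) form is used (Miller's tabled values agree
## with it to the printed precision over 35-100).
.ks_crit_05 <- c(
  0.97500, 0.84189, 0.70760, 0.62394, 0.56328, 0.51926, 0.48342, 0.45427,
  0.43001, 0.40925, 0.39122, 0.37543, 0.36143, 0.34890, 0.33760, 0.32733,
  0.31796, 0.30936, 0.30143, 0.29408, 0.28724, 0.28087, 0.27490, 0.26931,
  0.26404, 0.25907, 0.25438, 0.24993, 0.24571, 0.24170, 0.23788, 0.23424,
  0.23076, 0.22743)
.ks_crit_01 <- c(
  0.99500, 0.92929, 0.82900, 0.73424, 0.66853, 0.61661, 0.57581, 0.54179,
  0.51332, 0.48893, 0.46770, 0.44905, 0.43247, 0.41762, 0.40420, 0.39201,
  0.38086, 0.37062, 0.36117, 0.35241, 0.34426, 0.33666, 0.32954, 0.32286,
  0.31657, 0.31063, 0.30502, 0.29971, 0.29466, 0.28986, 0.28529, 0.28094,
  0.27677, 0.27279)

## Lilliefors (1967) percentage points for the KS statistic when the normal
## parameters are estimated from the sample; tabled n, linear interpolation
## between tabled sizes, and the standard large-sample approximation
## (0.886/sqrt(n) at alpha .05, 1.031/sqrt(n) at .01) above n = 30.
.lillie_n <- c(4:20, 25, 30)
.lillie_05 <- c(0.381, 0.337, 0.319, 0.300, 0.285, 0.271, 0.258, 0.249,
                0.242, 0.234, 0.227, 0.220, 0.213, 0.206, 0.200, 0.195,
                0.190, 0.173, 0.161)
.lillie_01 <- c(0.417, 0.405, 0.364, 0.348, 0.331, 0.311, 0.294, 0.284,
                0.275, 0.268, 0.261, 0.257, 0.250, 0.245, 0.239, 0.235,
                0.231, 0.200, 0.187)

#' Critical coefficient of the Kolmogorov distribution
#'
#' `d_alpha = sqrt(-ln(alpha/2) / 2)`, the coefficient used to build
#' critical values of the KS statistic: 1.358, 1.628, 1.731, 1.949 at
#' alpha = 0.05, 0.01, 0.005, 0.001.
#'
#' @param alpha significance level in (0, 1).
#' @return the coefficient (dimensionless).
#' @export
d_alpha <- function(alpha) {
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must lie in (0, 1)")
  sqrt(-log(alpha / 2) / 2)
}

#' Critical value of the one-sample KS statistic
#'
#' Plain (fully specified reference) critical values come from the embedded
#' exact table for n below 35 and from `d_alpha(alpha)/sqrt(n)` above;
#' the Lilliefors-corrected values - appropriate when the normal mean and
#' SD are estimated from the same small sample - come from the embedded
#' Lilliefors table (n up to 30, interpolated between tabled sizes) with
#' the standard large-sample approximation beyond. The correction is
#' uniformly stricter (smaller thresholds), which is why it recovers
#' non-normal verdicts that the plain test misses on intervalized data.
#'
#' @param n effective sample size (>= 1; >= 4 for Lilliefors).
#' @param alpha 0.05 or 0.01 (the tabled levels).
#' @param corrected `"plain"` or `"lilliefors"`.
#' @return critical value of D.
#' @examples
#' ks_critical_value(400)          # 1.358.../20 = 0.0679
#' ks_critical_value(20, corrected = "lilliefors")   # 0.190
#' @export
ks_critical_value <- function(n, alpha = 0.05, corrected = c("plain", "lilliefors")) {
  corrected <- match.arg(corrected)
  if (corrected == "plain") {
    if (!alpha %in% c(0.05, 0.01) && n < 35)
      stop("only alpha = 0.05 and 0.01 are tabled for n < 35")
    if (n < 35) {
      tab <- if (alpha == 0.05) .ks_crit_05 else .ks_crit_01
      return(tab[n])
    }
    return(d_alpha(alpha) / sqrt(n))
  }
  if (!alpha %in% c(0.05, 0.01)) stop("Lilliefors values are tabled for alpha = 0.05 and 0.01")
  if (n < 4) stop("Lilliefors table starts at n = 4")
  coefs <- if (alpha == 0.05) .lillie_05 else .lillie_01
  if (n > 30) return((if (alpha == 0.05) 0.886 else 1.031) / sqrt(n))
  stats::approx(.lillie_n, coefs, xout = n)$y
}

#' p-value of the KS statistic by Kolmogorov's series
#'
#' `P = 1 - L(z)` with `z = d * sqrt(n)` and
#' `L(z) = 1 - 2 * sum_{y>=1} (-1)^(y-1) exp(-2 y^2 z^2)`, truncated at
#' y = 10 (further terms are numerically irrelevant). Valid for both the
#' small intervalized samples and the large raw series.
#'
#' @param d KS statistic (>= 0).
#' @param n effective sample size.
#' @return p-value, capped into `[0, 1]`.
#' @export
kolmogorov_pvalue <- function(d, n) {
  if (any(d < 0)) stop("d must be non-negative")
  z <- d * sqrt(n)
  y <- 1:10
  p <- vapply(z, function(zi) 2 * sum((-1)^(y - 1) * exp(-2 * y^2 * zi^2)), numeric(1))
  pmin(pmax(p, 0), 1)
}

#' p-value of the KS statistic by Marsaglia's approximation
#'
#' `P = 2 * exp(-(2.000071 + 0.331/sqrt(n) + 1.409/n) * n * d^2)`. The raw
#' value can exceed 1 (it equals 2 at d = 0), which makes the formula
#' unusable for small samples; for n of 100 and up it agrees with
#' Kolmogorov's series in the third decimal place. By default the raw,
#' uncapped value is returned so the pathology is observable; set
#' `cap = TRUE` for `min(P, 1)`.
#'
#' @inheritParams kolmogorov_pvalue
#' @param cap cap the value at 1.
#' @return approximate p-value (possibly > 1 when `cap = FALSE`).
#' @export
marsaglia_pvalue <- function(d, n, cap = FALSE) {
  if (any(d < 0)) stop("d must be non-negative")
  p <- 2 * exp(-(2.000071 + 0.331 / sqrt(n) + 1.409 / n) * n * d^2)
  if (cap) pmin(p, 1) else p
}
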
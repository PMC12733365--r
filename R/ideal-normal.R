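#' Deterministic ideal normal mortality series
#'
#' Constructs the deaths-per-day series of a perfectly normal cohort from
#' three observables: the cohort size and the first and last days of
#' mortality. The underlying normal has its mean at the midpoint of the
#' mortality window and its SD anchored to the extreme order statistics:
#' `sigma = (last - first) / (2 * qnorm(1 - 1/(2 n)))`, so the first and
#' last mortality days sit at the median position of the cohort's extreme
#' order statistics (about half an expected death lies beyond each end of
#' the window); this is how the construction uses N. Day masses are
#' the window-renormalized normal CDF increments (with half-day continuity
#' correction) and are converted to integer counts by cumulative rounding,
#' which conserves the cohort size exactly.
#'
#' @param n cohort size (>= 1).
#' @param first_death,last_death first and last days of mortality
#'   (`first_death < last_death`, span of at least 3 days).
#' @return a [deaths_per_day()] object with counts summing exactly to `n`.
#' @examples
#' d <- ideal_normal_series(100, 0, 60)
#' sum(d$counts)          # exactly 100
#' @export
ideal_normal_series <- function(n, first_death, last_death) {
  d <- deaths_per_day(c(numeric(first_death),
                        .ideal_day_counts(n, first_death, last_death)))
  d
}

## bare counts on days first..last (no class overhead; sweep hot path)
.ideal_day_counts <- function(n, first, last) {
  if (last - first < 3) stop("mortality window must span at least 3 days")
  if (n < 1) stop("cohort size must be at least 1")
  days <- first:last
  mu <- (first + last) / 2
  sigma <- (last - first) / (2 * stats::qnorm(1 - 1 / (2 * n)))
  lo <- stats::pnorm(first - 0.5, mu, sigma)
  hi <- stats::pnorm(last + 0.5, mu, sigma)
  FF <- (stats::pnorm(days + 0.5, mu, sigma) - lo) / (hi - lo)
  diff(c(0, round(n * FF)))
}
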
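#' Sturges' rule interval width
#'
#' `C = R / (1 + 3.322 * log10(N)) = R / (1 + log2(N))`, the rule-of-thumb
#' optimal histogram interval size for a sample of size `N` spanning a range
#' of `R` days (maximum minus minimum lifespan).
#'
#' @param r day range of the sample (max - min), must be positive.
#' @param n sample size (number of individuals), at least 2.
#' @param rounding `"none"` returns the unrounded width; `"up"`, `"nearest"`
#'   and `"down"` round the width to whole days. Note the width/count
#'   duality: rounding the width *up* yields *fewer* intervals, and vice
#'   versa.
#' @return interval width in days.
#' @examples
#' sturges_width(64, 128)   # 8
#' sturges_width(64, 404)   # 6.626...
#' @seealso [sturges_count()] for the interval-count form of the rule.
#' @export
sturges_width <- function(r, n, rounding = c("none", "nearest", "up", "down")) {
  rounding <- match.arg(rounding)
  if (r <= 0) stop("day range must be positive")
  if (n < 2) stop("Sturges' rule needs a sample of at least 2")
  w <- r / (1 + log2(n))
  switch(rounding,
         none = w,
         nearest = max(round(w), 1),
         up = ceiling(w),
         down = max(floor(w), 1))
}

#' Sturges' rule interval count
#'
#' The interval-count form of Sturges' rule, `k = 1 + 3.322 * log10(N)`,
#' rounded under the requested mode. Here the mode names refer to the
#' arithmetic rounding of the count itself, so `"up"` yields *more*
#' intervals; this is the opposite vocabulary to width rounding (see
#' [sturges_width()]), where rounding the width up decreases the count.
#'
#' @param n sample size, at least 2.
#' @param rounding rounding mode applied to the count.
#' @return integer number of intervals.
#' @examples
#' sturges_count(128)            # 8 exactly
#' sturges_count(404, "down")    # 9
#' sturges_count(404, "up")      # 10
#' @export
sturges_count <- function(n, rounding = c("nearest", "up", "down")) {
  rounding <- match.arg(rounding)
  if (n < 2) stop("Sturges' rule needs a sample of at least 2")
  k <- 1 + log2(n)
  as.integer(switch(rounding, nearest = round(k), up = ceiling(k), down = floor(k)))
}

#' Interval scheme
#'
#' Describes a contiguous binning of the day axis: the first interval starts
#' at `start_day` and every interval is `width` days long. Widths may be
#' fractional (as produced by interval-count equalization). For whole-day
#' widths intervals are the half-open day spans
#' `[start, start + width)`, i.e. days 0-4, 5-9, ... for the default
#' 5-day scheme; for fractional widths membership follows the cumulative
#' boundary rule: an individual belongs to the first interval whose upper
#' boundary its lifespan does not exceed, so a lifespan exactly on a
#' boundary falls in the earlier interval. The two rules coincide on whole
#' days.
#'
#' @param start_day first day of the first interval (0-4).
#' @param width interval length in days (> 0, possibly fractional).
#' @param k number of intervals, or `NULL` to size the scheme to the data
#'   when binning.
#' @return an `interval_scheme` object.
#' @export
interval_scheme <- function(start_day = 0, width = 5, k = NULL) {
  if (width <= 0) stop("interval width must be positive")
  if (start_day < 0 || start_day > 4) stop("start_day must be between 0 and 4")
  if (!is.null(k) && k < 1) stop("k must be at least 1")
  structure(list(start_day = start_day, width = width, k = k),
            class = "interval_scheme")
}

## cumulative deaths through (integer) day d, given counts on days first..last
.cum_through_day <- function(cum, first, last, d) {
  d <- floor(d)
  out <- numeric(length(d))
  out[d >= last] <- cum[length(cum)]
  mid <- d >= first & d < last
  out[mid] <- cum[d[mid] - first + 1]
  out
}

## core binning: returns counts per interval for integer-day data given as
## per-day counts on days first..last. Origin may lie above `first`; it is
## extended left by whole widths so every death is covered.
.bin_day_counts <- function(day_counts, first, width, start_day, k = NULL,
                            rule = c("auto", "halfopen", "cumulative"),
                            min_day = first) {
  rule <- match.arg(rule)
  if (rule == "auto") rule <- if (width == round(width)) "halfopen" else "cumulative"
  last <- first + length(day_counts) - 1L
  origin <- start_day
  while (origin > min_day) origin <- origin - width
  if (is.null(k)) {
    k <- if (rule == "halfopen") floor((last - origin) / width) + 1
         else ceiling((last - origin) / width)
    k <- max(as.integer(k), 1L)
  }
  upper <- origin + seq_len(k) * width
  cover <- if (rule == "halfopen") upper[k] - 1 else floor(upper[k])
  if (cover < last)
    stop("interval scheme too short: ", k, " intervals of width ", width,
         " from day ", origin, " do not cover day ", last)
  ub_day <- if (rule == "halfopen") upper - 1 else floor(upper)
  cum <- cumsum(day_counts)
  cb <- .cum_through_day(cum, first, last, ub_day)
  list(counts = as.integer(diff(c(0, cb))), origin = origin, k = k, width = width)
}

#' Intervalize a lifespan series
#'
#' Bins a cohort into contiguous day intervals and returns the frequency
#' series of phenotypes by lifespan: per-interval death counts and the same
#' counts as percentages of the cohort. Binning smooths daily mortality
#' fluctuations (zero-mortality dips and one-day outliers) that otherwise
#' dominate small-sample normality tests.
#'
#' @param s a `lifespan_series` or `deaths_per_day` object.
#' @param scheme an [interval_scheme()]; alternatively give `width` /
#'   `start_day` / `k` directly.
#' @param width,start_day,k used when `scheme` is NULL.
#' @param rule bin-membership rule: `"halfopen"` day spans for whole-day
#'   widths, the `"cumulative"` upper-boundary rule for fractional widths
#'   (see [interval_scheme()]); `"auto"` picks by width. Interval-count
#'   equalization always uses the cumulative rule so the last boundary
#'   falls exactly on the maximum lifespan.
#' @return a `frequency_series` object with fields `counts`, `frequencies`
#'   (percentages summing to 100), `n`, `width`, `start_day` (origin of the
#'   first interval after any leftward extension), `breaks` (interval
#'   boundaries, length k + 1) and `k`.
#' @examples
#' f <- intervalize(lifespan_series(c(5, 6, 6, 8, 9, 10)))
#' f$counts        # 0 5 1 for days 0-4, 5-9, 10-14
#' @export
intervalize <- function(s, scheme = NULL, width = 5, start_day = 0, k = NULL,
                        rule = c("auto", "halfopen", "cumulative")) {
  d <- as_deaths(s)
  if (!is.null(scheme)) {
    stopifnot(inherits(scheme, "interval_scheme"))
    width <- scheme$width; start_day <- scheme$start_day; k <- scheme$k
  }
  b <- .bin_day_counts(d$counts, 0L, width, start_day, k, rule = match.arg(rule),
                       min_day = d$first_death_day)
  new_frequency_series(b$counts, n = d$n, width = width, start_day = b$origin)
}

new_frequency_series <- function(counts, n, width, start_day,
                                 display_only = FALSE, equalized = FALSE) {
  structure(list(
    counts = as.integer(counts),
    frequencies = 100 * counts / n,
    n = n,
    width = width,
    start_day = start_day,
    breaks = start_day + (0:length(counts)) * width,
    k = length(counts),
    display_only = display_only,
    equalized = equalized
  ), class = "frequency_series")
}

#' @export
print.frequency_series <- function(x, ...) {
  lab <- sprintf("[%g, %g)", x$breaks[-length(x$breaks)], x$breaks[-1])
  cat("Frequency series: n =", x$n, ", ", x$k, "intervals of width",
      signif(x$width, 4), "days", if (x$display_only) "(display only)" else "", "\n")
  print(data.frame(interval = lab, count = x$counts,
                   frequency = round(x$frequencies, 3)), row.names = FALSE)
  invisible(x)
}

#' Trim empty edge intervals from a frequency series
#'
#' Leading and trailing zero-count intervals must be excluded before
#' normality testing: an empty edge bin enters the test sample as an extra
#' observation of 0, shifting the empirical CDF relative to the rank/N
#' function (KS) and changing the number and composition of the W
#' coefficients (SW), which distorts both statistics and p-values.
#' Interior zero intervals are genuine mortality dips and are retained.
#'
#' @param f a `frequency_series`.
#' @param where which end(s) to trim.
#' @return the trimmed `frequency_series`; `n` is unchanged.
#' @export
trim_zero_intervals <- function(f, where = c("both", "leading", "trailing")) {
  where <- match.arg(where)
  stopifnot(inherits(f, "frequency_series"))
  nz <- which(f$counts > 0L)
  if (length(nz) == 0L) stop("all intervals are empty")
  from <- if (where %in% c("both", "leading")) nz[1L] else 1L
  to <- if (where %in% c("both", "trailing")) nz[length(nz)] else f$k
  new_frequency_series(f$counts[from:to], n = f$n, width = f$width,
                       start_day = f$start_day + (from - 1L) * f$width,
                       equalized = f$equalized)
}

#' Pad a frequency series with trailing zero intervals (display only)
#'
#' Appends empty intervals so two cohorts can be drawn over the same axis.
#' The result is flagged `display_only`; normality tests refuse it, because
#' artificial zero intervals distort the test statistics (see
#' [trim_zero_intervals()]).
#'
#' @param f a `frequency_series`.
#' @param k_target total number of intervals after padding (>= `f$k`).
#' @return a padded, display-only `frequency_series`.
#' @export
pad_zero_intervals <- function(f, k_target) {
  stopifnot(inherits(f, "frequency_series"))
  if (k_target < f$k) stop("k_target must be at least the current interval count")
  if (k_target == f$k) return(f)
  new_frequency_series(c(f$counts, integer(k_target - f$k)), n = f$n,
                       width = f$width, start_day = f$start_day,
                       display_only = TRUE)
}

#' Equalize interval counts between two cohorts
#'
#' For a paired comparison the two samples must have the same *number* of
#' intervals (interval sizes may differ and be fractional). The common count
#' is the smaller of the two Sturges counts (nearest rounding); each sample
#' is then binned from day 0 with its own width, maximum lifespan divided by
#' the common count. Leading zero intervals are removed only when empty in
#' *both* samples; an interval empty in just one sample is kept so the
#' counts stay aligned.
#'
#' @param a,b `lifespan_series` (or `deaths_per_day`) objects.
#' @return list with elements `a` and `b`, equalized `frequency_series`.
#' @export
equalize_pair <- function(a, b) {
  a <- as_lifespans(a); b <- as_lifespans(b)
  if (max(a) == min(a) || max(b) == min(b))
    stop("degenerate series: zero lifespan range")
  k <- min(sturges_count(length(a)), sturges_count(length(b)))
  fa <- intervalize(a, width = max(a) / k, start_day = 0, k = k, rule = "cumulative")
  fb <- intervalize(b, width = max(b) / k, start_day = 0, k = k, rule = "cumulative")
  drop <- 0L
  while (drop < k - 1L && fa$counts[drop + 1L] == 0L && fb$counts[drop + 1L] == 0L)
    drop <- drop + 1L
  if (drop > 0L) {
    fa <- new_frequency_series(fa$counts[-seq_len(drop)], n = fa$n, width = fa$width,
                               start_day = fa$start_day + drop * fa$width)
    fb <- new_frequency_series(fb$counts[-seq_len(drop)], n = fb$n, width = fb$width,
                               start_day = fb$start_day + drop * fb$width)
  }
  fa$equalized <- fb$equalized <- TRUE
  list(a = fa, b = fb)
}
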
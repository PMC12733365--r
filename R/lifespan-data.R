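#' Lifespan series
#'
#' A lifespan series holds one lifespan value, in whole days, per individual
#' in a fully observed cohort. It is the fundamental sample on which all
#' distribution analysis in this package operates. Day indexing is 0-based:
#' an individual recorded as dying on day 0 has lifespan 0.
#'
#' @param values integer vector of lifespans in days, one per individual.
#'   Must be non-negative and integer-valued; at least one value.
#' @return An object of class `lifespan_series`: an integer vector with the
#'   cohort size available as `length()`.
#' @examples
#' s <- lifespan_series(c(5, 6, 6, 8, 9, 10))
#' mean_lifespan(s)
#' @export
lifespan_series <- function(values) {
  if (length(values) < 1L) stop("empty cohort: a lifespan series needs at least one individual")
  if (anyNA(values)) stop("lifespan series contains missing values")
  if (any(values < 0)) stop("lifespans must be non-negative day counts")
  if (any(values != round(values))) stop("lifespans must be integer-valued (whole days)")
  structure(as.integer(sort(values)), class = "lifespan_series")
}

#' Deaths-per-day series
#'
#' The raw recording format of a survival assay: the number of individuals
#' that died on each calendar day, from day 0 through the last day of
#' mortality.
#'
#' @param counts non-negative integer vector of death counts; `counts[i]` is
#'   the number of deaths on day `i - 1` (day indexing starts at 0).
#' @return An object of class `deaths_per_day` with fields `counts` (full
#'   vector from day 0), `first_death_day`, `last_death_day` and `n`.
#' @examples
#' d <- deaths_per_day(c(0, 2, 0, 1))   # two deaths on day 1, one on day 3
#' as_lifespans(d)
#' @export
deaths_per_day <- function(counts) {
  if (anyNA(counts)) stop("death counts contain missing values")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("death counts must be non-negative integers")
  counts <- as.integer(counts)
  nz <- which(counts > 0L)
  if (length(nz) == 0L) stop("empty cohort: all death counts are zero")
  structure(list(
    counts = counts[seq_len(nz[length(nz)])],
    first_death_day = nz[1L] - 1L,
    last_death_day  = nz[length(nz)] - 1L,
    n = sum(counts)
  ), class = "deaths_per_day")
}

#' @export
print.lifespan_series <- function(x, ...) {
  cat("Lifespan series: n =", length(x), " range", min(x), "-", max(x), "days\n")
  print(unclass(x), ...)
  invisible(x)
}

#' @export
print.deaths_per_day <- function(x, ...) {
  cat("Deaths per day: n =", x$n, ", first death day", x$first_death_day,
      ", last death day", x$last_death_day, "\n")
  nz <- which(x$counts > 0L)
  print(stats::setNames(x$counts[nz], nz - 1L), ...)
  invisible(x)
}

#' Convert deaths-per-day records to a lifespan series
#'
#' Expands the day-indexed death counts into one lifespan value per
#' individual: `counts[i]` copies of day `i`. The inverse of
#' [as_deaths()]; the round trip is the identity.
#'
#' @param d a `deaths_per_day` object (or a bare non-negative count vector,
#'   interpreted as counts from day 0).
#' @return a [lifespan_series()].
#' @export
as_lifespans <- function(d) {
  if (inherits(d, "lifespan_series")) return(d)
  if (!inherits(d, "deaths_per_day")) d <- deaths_per_day(d)
  days <- seq_along(d$counts) - 1L
  lifespan_series(rep.int(days, d$counts))
}

#' Convert a lifespan series to deaths-per-day records
#'
#' @param s a `lifespan_series` (or bare vector of lifespans in days).
#' @return a [deaths_per_day()] object with `counts[i]` equal to the
#'   multiplicity of day `i - 1` in the series.
#' @export
as_deaths <- function(s) {
  if (inherits(s, "deaths_per_day")) return(s)
  if (!inherits(s, "lifespan_series")) s <- lifespan_series(s)
  deaths_per_day(tabulate(unclass(s) + 1L, nbins = max(s) + 1L))
}

#' Mean lifespan
#'
#' The arithmetic mean of the lifespan series; identically
#' `sum(A_i * i) / N` when computed from the deaths-per-day form, where
#' `A_i` is the number of deaths on day `i`.
#'
#' @param s a `lifespan_series` or `deaths_per_day` object.
#' @return mean lifespan in days.
#' @export
mean_lifespan <- function(s) {
  if (inherits(s, "deaths_per_day"))
    return(sum(s$counts * (seq_along(s$counts) - 1)) / s$n)
  mean(as_lifespans(s))
}

#' Sample standard deviation of lifespan
#'
#' Square root of the sample variance with the `N - 1` denominator:
#' `sqrt(sum((i - mu)^2 * A_i) / (N - 1))`.
#'
#' @inheritParams mean_lifespan
#' @return standard deviation in days. Requires at least two individuals.
#' @export
sd_lifespan <- function(s) {
  s <- as_lifespans(s)
  if (length(s) < 2L) stop("variance undefined for a single individual")
  stats::sd(s)
}

#' Summary statistics of a lifespan series
#'
#' Mean, sample standard deviation, median and mode of the lifespans. The
#' median of an even-length series is the mean of the two central order
#' statistics. The mode is the most frequent lifespan value; on ties the
#' smallest tied value is returned and `multimodal` is set, since a repeated
#' mode makes mode-anchored fitting unreliable (see [beta_fit()]).
#'
#' @inheritParams mean_lifespan
#' @return a list of class `lifespan_summary` with fields `n`, `mu`, `sigma`
#'   (NA for n = 1), `median`, `mode`, `multimodal`, `min`, `max`.
#' @export
summary_stats <- function(s) {
  s <- as_lifespans(s)
  tab <- table(unclass(s))
  modes <- as.integer(names(tab)[tab == max(tab)])
  structure(list(
    n = length(s),
    mu = mean(s),
    sigma = if (length(s) >= 2L) stats::sd(s) else NA_real_,
    median = stats::median(unclass(s)),
    mode = min(modes),
    multimodal = length(modes) > 1L,
    min = min(s),
    max = max(s)
  ), class = "lifespan_summary")
}

#' @export
print.lifespan_summary <- function(x, ...) {
  cat(sprintf("n = %d, mean = %.2f, sd = %.2f, median = %g, mode = %d%s, range %d-%d days\n",
              x$n, x$mu, x$sigma, x$median, x$mode,
              if (x$multimodal) " (multimodal)" else "", x$min, x$max))
  invisible(x)
}

#' Read a cohort from a CSV/TSV file
#'
#' Two layouts are accepted, distinguished by the header: a deaths-per-day
#' table with columns `day,count` or a lifespan series with a single
#' `lifespan` column. The field separator (comma or tab) is sniffed from the
#' header line. Cells must be integer-valued.
#'
#' @param path file path.
#' @return a `lifespan_series` (lifespan layout) or `deaths_per_day` object.
#' @export
read_cohort <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, strip.white = TRUE)
  names(df) <- tolower(names(df))
  chk_int <- function(x, what) {
    if (anyNA(x) || !is.numeric(x) || any(x != round(x)))
      stop("column '", what, "' in ", path, " must be integer-valued")
    as.integer(x)
  }
  if (all(c("day", "count") %in% names(df))) {
    day <- chk_int(df$day, "day"); count <- chk_int(df$count, "count")
    counts <- integer(max(day) + 1L)
    counts[day + 1L] <- counts[day + 1L] + count
    deaths_per_day(counts)
  } else if ("lifespan" %in% names(df)) {
    lifespan_series(chk_int(df$lifespan, "lifespan"))
  } else {
    stop("unrecognised cohort layout in ", path,
         ": expected columns 'day,count' or a single 'lifespan' column")
  }
}

#' Write a cohort to a CSV/TSV file
#'
#' @param x a `lifespan_series` or `deaths_per_day` object.
#' @param path output file path; a `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  if (inherits(x, "deaths_per_day")) {
    nz <- which(x$counts > 0L)
    df <- data.frame(day = nz - 1L, count = x$counts[nz])
  } else {
    df <- data.frame(lifespan = as.integer(as_lifespans(x)))
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
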
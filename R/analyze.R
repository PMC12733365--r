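#' Analysis configuration
#'
#' Collects the tunable parameters of the analysis pipeline with the
#' package defaults: 5-day intervals starting on day 0, alpha 0.05,
#' Kolmogorov p-values for the KS test.
#'
#' @param interval.width interval width in days, or `"sturges"` to use
#'   Sturges' rule (nearest width rounding).
#' @param interval.start_day first day of the first interval (0-4).
#' @param alpha significance level for all verdicts.
#' @param ks.method one-sample KS p-value method.
#' @return a named list of class `lifedist_config`.
#' @export
lifedist_config <- function(interval.width = 5, interval.start_day = 0,
                            alpha = 0.05,
                            ks.method = c("kolmogorov", "marsaglia", "lilliefors")) {
  structure(list(interval.width = interval.width,
                 interval.start_day = interval.start_day,
                 alpha = alpha, ks.method = match.arg(ks.method)),
            class = "lifedist_config")
}

.resolve_width <- function(cfg, s) {
  if (identical(cfg$interval.width, "sturges"))
    sturges_width(max(s) - min(s), length(s), "nearest")
  else cfg$interval.width
}

#' Analyse a single cohort
#'
#' Runs the full single-sample pipeline: summary statistics, the chosen
#' interval scheme, Shapiro-Wilk tests on the raw series (full Royston
#' method) and on the trimmed intervalized series (hybrid test), one-sample
#' KS tests on both forms, and normal/beta overlay fits. Deterministic:
#' identical input and configuration give an identical report. Every
#' number in the report is the untouched output of the corresponding
#' operation.
#'
#' @param x a cohort: file path, `lifespan_series` or `deaths_per_day`.
#' @param config a [lifedist_config()].
#' @param id cohort label used in printed reports.
#' @return an `analysis_report`; see [as.data.frame.analysis_report()] for
#'   the tabular form.
#' @export
analyze_cohort <- function(x, config = lifedist_config(), id = NULL) {
  if (is.character(x)) {
    if (is.null(id)) id <- sub("\\.(csv|tsv)$", "", basename(x))
    x <- read_cohort(x)
  }
  s <- as_lifespans(x)
  if (length(s) < 3) stop("cohort too small: need at least 3 individuals")
  if (is.null(id)) id <- "cohort"
  st <- summary_stats(s)
  f <- trim_zero_intervals(
    intervalize(s, width = .resolve_width(config, s),
                start_day = config$interval.start_day))
  sw_raw <- if (length(s) >= 12 && length(s) <= 5000)
    sw_test_royston(s, config$alpha) else NULL
  sw_int <- sw_test_hybrid(f, config$alpha, warn_small = FALSE)
  ks_raw <- ks_one_sample(s, config$alpha, method = config$ks.method)
  ks_int <- ks_one_sample(f, config$alpha, method = config$ks.method)
  ks_int_lillie <- tryCatch(ks_one_sample(f, config$alpha, method = "lilliefors"),
                            error = function(e) NULL)
  beta <- beta_fit(s, f)
  structure(list(id = id, n = length(s), series = s, stats = st, scheme = f,
                 sw_raw = sw_raw, sw_int = sw_int,
                 ks_raw = ks_raw, ks_int = ks_int,
                 ks_int_lilliefors = ks_int_lillie,
                 beta = beta,
                 normal = list(mu = st$mu, sigma = st$sigma),
                 config = config),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Cohort", x$id, "==\n")
  print(x$stats)
  cat(sprintf("Intervals: %d of width %.3g days from day %g\n",
              x$scheme$k, x$scheme$width, x$scheme$start_day))
  if (!is.null(x$sw_raw)) { cat("Raw series       "); print(x$sw_raw) }
  cat("Intervalized     "); print(x$sw_int)
  cat("Raw series       "); print(x$ks_raw)
  cat("Intervalized     "); print(x$ks_int)
  if (!is.null(x$ks_int_lilliefors)) {
    cat("Intervalized     "); print(x$ks_int_lilliefors)
  }
  print(x$beta)
  invisible(x)
}

#' Tabulate an analysis report
#'
#' One row per cohort with the column layout of a lifespan-assay results
#' table: identifier, mean and SD, W and p of the SW test without and with
#' intervalization, D and p of the KS test without and with
#' intervalization, the two-sample KS result when present, the number of
#' intervals and the sample size.
#'
#' @param x an `analysis_report` or `comparison_report`.
#' @param row.names,optional,... passed through (unused).
#' @return a data.frame.
#' @export
as.data.frame.analysis_report <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    id = x$id,
    mu_days = x$stats$mu,
    sigma_days = x$stats$sigma,
    sw_raw_w = if (is.null(x$sw_raw)) NA_real_ else x$sw_raw$w,
    sw_raw_p = if (is.null(x$sw_raw)) NA_real_ else x$sw_raw$p,
    sw_raw_verdict = if (is.null(x$sw_raw)) NA_character_ else x$sw_raw$verdict,
    sw_int_w = x$sw_int$w,
    sw_int_p = x$sw_int$p,
    sw_int_verdict = x$sw_int$verdict,
    ks_raw_d = x$ks_raw$d,
    ks_raw_p = x$ks_raw$p,
    ks_raw_verdict = x$ks_raw$verdict,
    ks_int_d = x$ks_int$d,
    ks_int_p = x$ks_int$p,
    ks_int_verdict = x$ks_int$verdict,
    ks_int_lilliefors_verdict = if (is.null(x$ks_int_lilliefors)) NA_character_
                                else x$ks_int_lilliefors$verdict,
    two_sample_ks_p = NA_real_,
    two_sample_ks_verdict = NA_character_,
    n_intervals = x$scheme$k,
    n = x$n,
    stringsAsFactors = FALSE)
}

#' Compare two cohorts
#'
#' The paired pipeline: both cohorts are analysed individually, their
#' interval counts are equalized (Sturges counts, smaller of the two; see
#' [equalize_pair()]), the hybrid SW test is run on the equalized series,
#' and the survival curves are compared with the two-sample KS test.
#'
#' @param a,b cohorts: file paths, `lifespan_series` or `deaths_per_day`.
#' @param config a [lifedist_config()].
#' @param ids length-2 labels.
#' @return a `comparison_report`.
#' @export
compare_cohorts <- function(a, b, config = lifedist_config(), ids = NULL) {
  get_id <- function(x, default) {
    if (is.character(x)) sub("\\.(csv|tsv)$", "", basename(x)) else default
  }
  if (is.null(ids)) ids <- c(get_id(a, "a"), get_id(b, "b"))
  ra <- analyze_cohort(a, config, ids[1])
  rb <- analyze_cohort(b, config, ids[2])
  sa <- as_lifespans(if (is.character(a)) read_cohort(a) else a)
  sb <- as_lifespans(if (is.character(b)) read_cohort(b) else b)
  eq <- equalize_pair(sa, sb)
  sw_eq <- list(a = sw_test_hybrid(eq$a, config$alpha, warn_small = FALSE),
                b = sw_test_hybrid(eq$b, config$alpha, warn_small = FALSE))
  ks2 <- ks_two_sample(sa, sb, alpha = config$alpha)
  structure(list(a = ra, b = rb, equalized = eq, sw_equalized = sw_eq,
                 ks_two_sample = ks2, config = config),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  print(x$a); cat("\n"); print(x$b)
  cat(sprintf("\nEqualized intervals: k = %d (widths %.3g / %.3g days)\n",
              x$equalized$a$k, x$equalized$a$width, x$equalized$b$width))
  cat("  ", x$a$id, ": "); print(x$sw_equalized$a)
  cat("  ", x$b$id, ": "); print(x$sw_equalized$b)
  cat("\nSurvival curves: "); print(x$ks_two_sample)
  invisible(x)
}

#' @rdname as.data.frame.analysis_report
#' @export
as.data.frame.comparison_report <- function(x, row.names = NULL, optional = FALSE, ...) {
  df <- rbind(as.data.frame(x$a), as.data.frame(x$b))
  df$sw_eq_w <- c(x$sw_equalized$a$w, x$sw_equalized$b$w)
  df$sw_eq_p <- c(x$sw_equalized$a$p, x$sw_equalized$b$p)
  df$sw_eq_verdict <- c(x$sw_equalized$a$verdict, x$sw_equalized$b$verdict)
  df$n_intervals_eq <- c(x$equalized$a$k, x$equalized$b$k)
  df$interval_width_eq <- c(x$equalized$a$width, x$equalized$b$width)
  df$two_sample_ks_p <- x$ks_two_sample$p
  df$two_sample_ks_verdict <- x$ks_two_sample$verdict
  df
}

#' Serialize a report to JSON
#'
#' @param x an `analysis_report` or `comparison_report`.
#' @param path optional output file; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
report_json <- function(x, path = NULL) {
  js <- jsonlite::toJSON(as.data.frame(x), digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
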
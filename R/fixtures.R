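#' Synthetic lifespan cohorts
#'
#' Generates reproducible synthetic cohorts with the distribution shapes
#' observed in real lifespan assays: a symmetric bell shape, left- and
#' right-skewed beta shapes, and a uniform (plateau-like) shape. Lifespans
#' are drawn over `[first_death, first_death + span]` and rounded to whole
#' days; draws are seeded, so a fixed seed yields an identical cohort.
#'
#' @param shape one of `"normal"`, `"left-beta"` (long left tail, mass late
#'   in life), `"right-beta"` (long right tail, mass early), `"uniform"`.
#' @param n cohort size.
#' @param span width of the mortality window in days.
#' @param first_death first possible day of death.
#' @param seed integer seed.
#' @return a [lifespan_series()].
#' @examples
#' fixture_cohort("left-beta", 150, 60, seed = 1)
#' @export
fixture_cohort <- function(shape = c("normal", "left-beta", "right-beta", "uniform"),
                           n, span = 60, first_death = 5, seed = 1) {
  shape <- match.arg(shape)
  if (n < 1) stop("cohort size must be at least 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  u <- switch(shape,
              normal = stats::qnorm(stats::runif(n, stats::pnorm(-3), stats::pnorm(3))) / 6 + 0.5,
              `left-beta` = stats::rbeta(n, 5, 1.8),
              `right-beta` = stats::rbeta(n, 1.8, 5),
              uniform = stats::runif(n))
  lifespan_series(round(first_death + u * span))
}
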
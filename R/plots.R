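#' Plot a frequency series with overlay curves
#'
#' Bars of the per-interval mortality frequencies with optional normal
#' and/or beta overlay curves and a survival-curve inset, the standard
#' presentation of a lifespan frequency distribution.
#'
#' @param x a `frequency_series`.
#' @param report optional `analysis_report` supplying the overlays and the
#'   survival inset.
#' @param overlays which curves to draw when a report is given.
#' @param main plot title.
#' @param col bar colour.
#' @param inset draw the survival-curve inset (needs `report`).
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
plot.frequency_series <- function(x, report = NULL,
                                  overlays = c("normal", "beta"),
                                  main = NULL, col = "grey70",
                                  inset = !is.null(report), ...) {
  mids <- graphics::barplot(x$frequencies, width = x$width, space = 0,
                            names.arg = sprintf("%g", x$breaks[-length(x$breaks)]),
                            xlab = "lifespan interval start (days)",
                            ylab = "mortality frequency (%)",
                            main = main, col = col, ...)
  if (!is.null(report)) {
    day2x <- function(day) (day - x$start_day) / x$width * x$width  # bar units
    if ("normal" %in% overlays && !is.na(report$normal$sigma)) {
      ov <- normal_overlay(report$normal$mu, report$normal$sigma,
                           "frequency", width = x$width,
                           days = seq(x$start_day, max(x$breaks), by = 0.5))
      graphics::lines(day2x(ov$day), ov$y, lwd = 2)
    }
    if ("beta" %in% overlays) {
      bo <- beta_overlay(report$beta, x)
      graphics::lines(day2x(bo$day), bo$y, lwd = 2, lty = 2)
    }
    if (inset) {
      sc <- survival_curve(report$series)
      op <- graphics::par(fig = c(0.62, 0.98, 0.55, 0.95), new = TRUE,
                          mar = c(2, 2, 0.5, 0.5), cex = 0.6)
      on.exit(graphics::par(op))
      graphics::plot(sc$day, sc$s, type = "s", xlab = "", ylab = "S(t)")
    }
  }
  invisible(mids)
}

#' Plot survival curves of one or two cohorts
#'
#' @param x a `survival_curve`.
#' @param y optional second `survival_curve`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.survival_curve <- function(x, y = NULL, ...) {
  graphics::plot(x$day, x$s, type = "s", xlab = "day",
                 ylab = "fraction surviving", ylim = c(0, 1), ...)
  if (!is.null(y)) graphics::lines(y$day, y$s, type = "s", lty = 2)
  invisible(x)
}
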
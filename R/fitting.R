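#' Scaled normal overlay curve
#'
#' Evaluates the normal PDF with the cohort's mean and SD - always taken
#' from the raw, non-intervalized lifespans, since the SD of intervalized
#' data is inflated by the binning - and scales it to sit over a mortality
#' plot: multiplied by the cohort size N for deaths-per-day bars, or by
#' 100 (the total frequency mass) times the interval width for frequency
#' bars.
#'
#' @param mu,sigma mean and SD in days, from the raw series (`sigma > 0`).
#' @param scale_mode `"deaths"` or `"frequency"`.
#' @param n cohort size (deaths scaling).
#' @param width interval width in days (frequency scaling).
#' @param days evaluation days (default 0 to `mu + 4 sigma`, per day).
#' @return a `normal_overlay`: list with `day`, `y` (scaled curve), `mu`,
#'   `sigma`, `scale_mode`, `scale_factor`.
#' @export
normal_overlay <- function(mu, sigma, scale_mode = c("deaths", "frequency"),
                           n = NULL, width = NULL, days = NULL) {
  scale_mode <- match.arg(scale_mode)
  if (sigma <= 0) stop("sigma must be positive")
  if (is.null(days)) days <- 0:ceiling(mu + 4 * sigma)
  sf <- if (scale_mode == "deaths") {
    if (is.null(n)) stop("deaths scaling needs the cohort size n")
    n
  } else {
    if (is.null(width)) stop("frequency scaling needs the interval width")
    100 * width
  }
  structure(list(day = days, y = sf * stats::dnorm(days, mu, sigma),
                 mu = mu, sigma = sigma, scale_mode = scale_mode,
                 scale_factor = sf),
            class = "normal_overlay")
}

#' Beta distribution density
#'
#' `x^(p-1) (1-x)^(q-1) / B(p, q)` on the unit interval. For `p, q > 1`
#' the density is 0 at both endpoints, which is what makes the beta overlay
#' close onto the x-axis at the first and last mortality days (unlike the
#' normal PDF, which never reaches 0).
#'
#' @param x values in `[0, 1]`.
#' @param p,q positive shape parameters.
#' @return densities.
#' @export
beta_pdf <- function(x, p, q) {
  if (p <= 0 || q <= 0) stop("shape parameters must be positive")
  if (any(x < 0 | x > 1)) stop("x must lie in [0, 1]")
  stats::dbeta(x, p, q)
}

#' Map a day value onto the unit interval of the beta fit
#'
#' `(value - first)/(last - first)`: the beta distribution lives on (0, 1),
#' so day statistics are normalized by the observed mortality window before
#' the shape parameters are solved.
#'
#' @param value day value in `[first, last]`.
#' @param first,last first and last days of mortality (`first < last`).
#' @return value on the unit interval.
#' @examples
#' normalize_to_unit(35, 8, 84)   # 27/76 = 0.3553
#' @export
normalize_to_unit <- function(value, first, last) {
  if (last <= first) stop("mortality window has zero length")
  if (any(value < first | value > last)) stop("value outside the mortality window")
  (value - first) / (last - first)
}

#' Beta shape parameters from mean and median
#'
#' Closed-form solution using the beta median approximation
#' `Med = (p - 1/3)/(p + q - 2/3)`: substituting `q = p/mu - p` gives
#' `p = (mu/3) (2 Med - 1)/(Med - mu)` and `q = p/mu - p`. The returned
#' pair reproduces `mu = p/(p + q)` exactly and `Med` through the same
#' approximation. Values of p or q below 1 signal that no valid
#' median-anchored beta exists for this pair (the caller falls back).
#'
#' @param mu_norm,med_norm normalized mean and median in (0, 1),
#'   `med_norm != mu_norm`.
#' @return named vector `c(p =, q =)`.
#' @examples
#' beta_params_from_median(0.4, 0.38)   # p = 1.6, q = 2.4
#' @export
beta_params_from_median <- function(mu_norm, med_norm) {
  stopifnot(mu_norm > 0, mu_norm < 1, med_norm > 0, med_norm < 1)
  if (med_norm == mu_norm) stop("median equals mean: median anchor degenerate")
  p <- (mu_norm / 3) * (2 * med_norm - 1) / (med_norm - mu_norm)
  c(p = p, q = p / mu_norm - p)
}

#' Beta shape parameters from mean and mode
#'
#' Closed form obtained by substituting `q = p/mu - p` into the beta mode
#' `Mode = (p - 1)/(p + q - 2)`: `p = mu (2 Mode - 1)/(Mode - mu)` and
#' `q = p/mu - p`. Accepted fits reproduce the mode exactly through the
#' same formula. The mode anchor fails (division by zero) on symmetric
#' input where `Mode = mu`.
#'
#' @param mu_norm,mode_norm normalized mean and mode in (0, 1),
#'   `mode_norm != mu_norm`.
#' @return named vector `c(p =, q =)`.
#' @examples
#' beta_params_from_mode(1/3, 0.25)   # p = 2, q = 4
#' @export
beta_params_from_mode <- function(mu_norm, mode_norm) {
  stopifnot(mu_norm > 0, mu_norm < 1, mode_norm > 0, mode_norm < 1)
  if (mode_norm == mu_norm) stop("mode equals mean: mode anchor degenerate")
  p <- mu_norm * (2 * mode_norm - 1) / (mode_norm - mu_norm)
  c(p = p, q = p / mu_norm - p)
}

## interval-level mode (midpoint of the modal interval) and median
## (linearly interpolated within the median interval) of a frequency series
.interval_mode <- function(f) {
  i <- which.max(f$counts)
  multim <- sum(f$counts == f$counts[i]) > 1L
  list(mode = (f$breaks[i] + f$breaks[i + 1L]) / 2, multimodal = multim)
}

.interval_median <- function(f) {
  cum <- cumsum(f$counts)
  half <- f$n / 2
  i <- which(cum >= half)[1L]
  below <- if (i == 1L) 0 else cum[i - 1L]
  f$breaks[i] + (half - below) / f$counts[i] * f$width
}

#' Automatic beta-distribution fit of a lifespan cohort
#'
#' Fits a beta distribution over the observed mortality window by a fixed
#' decision tree. Candidate anchors are tried in order until one yields
#' valid shapes (`p >= 1` and `q >= 1`): mode then median computed from the
#' intervalized series (interval mode = midpoint of the modal interval,
#' interval median interpolated within the median interval), then mode and
#' median of the original series; if none is valid the lower edge of the
#' normalization window is advanced one day at a time (`initial_day` up to
#' 4, re-deriving the statistics each time). If every candidate fails the
#' default symmetric bell shape `p = q = 3.5` is returned. The chosen
#' anchor, series type and `initial_day` are recorded; the tree is fully
#' deterministic.
#'
#' @param s a `lifespan_series` (or `deaths_per_day`).
#' @param f the matching intervalized `frequency_series`; computed with the
#'   default 5-day scheme (trimmed) when NULL.
#' @param initial_day starting value of the window-shift indicator (0-4).
#' @param anchor optional override: force `"mode"`, `"median"` or
#'   `"default"` instead of running the tree.
#' @return a `beta_fit`: list with `p`, `q`, `anchor`
#'   (`"mode"`/`"median"`/`"default"`), `series` (`"interval"`/`"original"`),
#'   `initial_day`, `first_death`, `last_death` (the normalization window).
#' @export
beta_fit <- function(s, f = NULL, initial_day = 0,
                     anchor = c("auto", "mode", "median", "default")) {
  anchor <- match.arg(anchor)
  s <- as_lifespans(s)
  if (is.null(f)) f <- trim_zero_intervals(intervalize(s))
  st <- summary_stats(s)
  first0 <- st$min; last <- st$max
  if (anchor == "default")
    return(structure(list(p = 3.5, q = 3.5, anchor = "default",
                          series = NA_character_, initial_day = initial_day,
                          first_death = first0, last_death = last),
                     class = "beta_fit"))
  valid <- function(pq) all(is.finite(pq)) && pq[1] >= 1 && pq[2] >= 1
  try_anchor <- function(fun, mu, stat, first) {
    if (last <= first || mu <= first || mu >= last ||
        stat <= first || stat >= last) return(NULL)
    mu_n <- normalize_to_unit(mu, first, last)
    st_n <- normalize_to_unit(stat, first, last)
    if (st_n == mu_n) return(NULL)
    pq <- tryCatch(fun(mu_n, st_n), error = function(e) NULL)
    if (!is.null(pq) && valid(pq)) pq else NULL
  }
  done <- function(pq, anc, ser, init)
    structure(list(p = unname(pq[1]), q = unname(pq[2]), anchor = anc,
                   series = ser, initial_day = init,
                   first_death = first0 + init, last_death = last),
              class = "beta_fit")
  for (init in initial_day:4) {
    first <- first0 + init
    fi <- if (init == 0) f else
      tryCatch(trim_zero_intervals(intervalize(s, width = f$width, start_day = init %% 5)),
               error = function(e) NULL)
    if (!is.null(fi)) {
      im <- .interval_mode(fi)
      if (anchor %in% c("auto", "mode") && !im$multimodal) {
        pq <- try_anchor(beta_params_from_mode, st$mu, im$mode, first)
        if (!is.null(pq)) return(done(pq, "mode", "interval", init))
      }
      if (anchor %in% c("auto", "median")) {
        pq <- try_anchor(beta_params_from_median, st$mu, .interval_median(fi), first)
        if (!is.null(pq)) return(done(pq, "median", "interval", init))
      }
    }
    if (anchor %in% c("auto", "mode") && !st$multimodal) {
      pq <- try_anchor(beta_params_from_mode, st$mu, st$mode, first)
      if (!is.null(pq)) return(done(pq, "mode", "original", init))
    }
    if (anchor %in% c("auto", "median")) {
      pq <- try_anchor(beta_params_from_median, st$mu, st$median, first)
      if (!is.null(pq)) return(done(pq, "median", "original", init))
    }
    if (anchor != "auto") break
  }
  structure(list(p = 3.5, q = 3.5, anchor = "default", series = NA_character_,
                 initial_day = initial_day, first_death = first0,
                 last_death = last),
            class = "beta_fit")
}

#' @export
print.beta_fit <- function(x, ...) {
  cat(sprintf("Beta fit: p = %.3f, q = %.3f (anchor %s%s, initial day %d), window %d-%d days\n",
              x$p, x$q, x$anchor,
              if (!is.na(x$series)) paste0(" on ", x$series, " series") else "",
              x$initial_day, x$first_death, x$last_death))
  invisible(x)
}

#' Evaluate a beta fit as an overlay curve in day units
#'
#' Samples the fitted beta PDF at `n_points` evenly spaced points of the
#' unit interval (dense sampling avoids the angular look of per-interval
#' evaluation), maps them back to days, and scales the curve to match the
#' total mass of the frequency bars so the two are drawn on the same axis.
#'
#' @param fit a `beta_fit`.
#' @param f the `frequency_series` the curve will overlay.
#' @param n_points number of curve samples.
#' @return data.frame with columns `day` and `y`.
#' @export
beta_overlay <- function(fit, f, n_points = 200) {
  stopifnot(inherits(fit, "beta_fit"), inherits(f, "frequency_series"))
  u <- seq(0, 1, length.out = n_points)
  day <- fit$first_death + u * (fit$last_death - fit$first_death)
  dens <- stats::dbeta(u, fit$p, fit$q) / (fit$last_death - fit$first_death)
  mass <- sum(f$frequencies)   # 100 for a full series
  data.frame(day = day, y = dens * mass * f$width)
}
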
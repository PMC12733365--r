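# Independent brute-force oracles used to check the package's closed-form
# and vectorized implementations on small inputs.

# assign each individual to an interval by scanning boundaries one at a time
oracle_bin <- function(values, width, start_day = 0, k = NULL,
                       rule = c("auto", "halfopen", "cumulative")) {
  rule <- match.arg(rule)
  if (rule == "auto") rule <- if (width == round(width)) "halfopen" else "cumulative"
  origin <- start_day
  while (origin > min(values)) origin <- origin - width
  if (is.null(k)) k <- ceiling((max(values) - origin + 1) / width)
  counts <- integer(k)
  for (x in values) {
    for (j in seq_len(k)) {
      hit <- if (rule == "halfopen") {
        x >= origin + (j - 1) * width && x < origin + j * width
      } else {
        x <= origin + j * width && (j == 1 || x > origin + (j - 1) * width)
      }
      if (hit) { counts[j] <- counts[j] + 1L; break }
    }
  }
  counts
}

# supremum gap between the ECDF of x and Normal(mu, sigma) by dense scan
oracle_ks_d <- function(x, mu, sigma) {
  n <- length(x)
  sx <- sort(x)
  best <- 0
  for (v in unique(sx)) {
    ec_hi <- sum(sx <= v) / n
    ec_lo <- sum(sx < v) / n
    ref <- pnorm(v, mu, sigma)
    best <- max(best, abs(ec_hi - ref), abs(ec_lo - ref))
  }
  best
}

# two-sample sup gap over all integer days
oracle_ks2_d <- function(a, b) {
  days <- 0:max(max(a), max(b))
  Fa <- sapply(days, function(d) mean(a <= d))
  Fb <- sapply(days, function(d) mean(b <= d))
  max(abs(Fa - Fb))
}

new_frequency_series_for_test <- function(counts) {
  lifedist:::new_frequency_series(counts, n = sum(counts), width = 5, start_day = 0)
}

random_deaths_table <- function(seed) {
  set.seed(seed)
  tmax <- sample(5:40, 1)
  counts <- rpois(tmax + 1, lambda = runif(1, 0.2, 3))
  if (sum(counts) == 0) counts[sample(tmax + 1, 1)] <- 1L
  counts
}
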
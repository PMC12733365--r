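test_that("normal CDF matches tabled values and the erf quadrature", {
  expect_equal(normal_cdf(30, 30, 5), 0.5)
  expect_equal(normal_cdf(35, 30, 5), 0.8413, tolerance = 1e-4)
  # quadrature of the error-function integral
  erf_num <- function(z) 2 / sqrt(pi) * integrate(function(t) exp(-t^2), 0, z)$value
  for (x in c(-1.3, 0.4, 2.2)) {
    expect_equal(normal_cdf(x, 0, 1), 0.5 * (1 + erf_num(x / sqrt(2))),
                 tolerance = 1e-8)
  }
  expect_error(normal_cdf(1, 0, 0), "positive")
})

test_that("empirical CDF uses rank/N with tie collapse", {
  F1 <- empirical_cdf(c(1, 2, 3))
  expect_equal(F1(2), 2 / 3)
  expect_equal(empirical_cdf(c(2, 2))(2), 1)
  expect_equal(F1(0.5), 0); expect_equal(F1(3), 1)
})

test_that("critical coefficient d_alpha reproduces the tabled levels", {
  expect_equal(round(d_alpha(0.05), 3), 1.358)
  expect_equal(round(d_alpha(0.01), 3), 1.628)
  expect_equal(round(d_alpha(0.005), 3), 1.731)
  expect_equal(round(d_alpha(0.001), 3), 1.949)
  expect_true(all(diff(d_alpha(c(0.001, 0.01, 0.05, 0.2))) < 0))
  expect_error(d_alpha(0), "alpha")
})

test_that("Kolmogorov p-value series behaves as tabulated", {
  expect_equal(kolmogorov_pvalue(3, 1), 3.05e-8, tolerance = 1e-2)
  expect_equal(kolmogorov_pvalue(1.358, 1), 0.05, tolerance = 2e-3)
  # monotone decreasing in d
  p <- kolmogorov_pvalue(seq(0.05, 0.5, 0.05), 100)
  expect_true(all(diff(p) < 0))
  # cross-consistency with the d_alpha closed form at all four tabled levels
  for (a in c(0.05, 0.01, 0.005, 0.001)) {
    expect_equal(kolmogorov_pvalue(d_alpha(a), 1), a, tolerance = 2e-3)
  }
})

test_that("Marsaglia approximation matches Kolmogorov for large N and breaks below", {
  expect_equal(marsaglia_pvalue(0, 50), 2)          # exceeds 1 on degenerate input
  expect_equal(marsaglia_pvalue(0, 50, cap = TRUE), 1)
  expect_equal(marsaglia_pvalue(0.136, 100), 0.0453, tolerance = 1e-3)
  # agreement in the significance-decision region (z at and beyond the
  # alpha = 0.05 coefficient), where the verdicts are actually made
  for (n in c(100, 200, 500, 1000)) {
    d <- seq(1.36, 3, 0.2) / sqrt(n)
    expect_lt(max(abs(marsaglia_pvalue(d, n) - kolmogorov_pvalue(d, n))), 5e-3)
  }
  # the >1 pathology for small N * D^2
  expect_gt(marsaglia_pvalue(0.05, 10), 1)
})

test_that("one-sample KS critical values: table, asymptote, Lilliefors ordering", {
  expect_equal(ks_critical_value(400), 1.358 / 20, tolerance = 1e-3)
  expect_equal(ks_critical_value(10000), 0.0136, tolerance = 2e-3)
  expect_equal(ks_critical_value(10), 0.409, tolerance = 1e-3)
  expect_equal(ks_critical_value(20, corrected = "lilliefors"), 0.190)
  for (n in c(5, 10, 20, 30, 50, 200)) {
    expect_lt(ks_critical_value(n, corrected = "lilliefors"),
              ks_critical_value(n))
  }
})

test_that("one-sample KS statistic equals the brute-force supremum scan", {
  for (seed in 1:12) {
    s <- as_lifespans(deaths_per_day(random_deaths_table(seed)))
    if (length(s) < 3 || sd(s) == 0) next
    r <- ks_one_sample(s)
    expect_equal(r$d, oracle_ks_d(as.numeric(s), mean(s), sd(as.numeric(s))),
                 tolerance = 1e-12)
    # agreement with the reference implementation's statistic
    ref <- suppressWarnings(ks.test(as.numeric(s), "pnorm",
                                    mean(s), sd(as.numeric(s))))
    expect_equal(r$d, unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("one-sample KS on intervalized data uses the interval counts as sample", {
  f <- new_frequency_series_for_test(c(1L, 2L, 5L, 9L, 3L))
  r <- ks_one_sample(f)
  expect_equal(r$n, 5)                      # effective n = number of intervals
  cts <- c(1, 2, 5, 9, 3)
  expect_equal(r$d, oracle_ks_d(cts, mean(cts), sd(cts)), tolerance = 1e-12)

  # strongly non-normal count pattern is rejected at alpha 0.05
  r2 <- ks_one_sample(new_frequency_series_for_test(c(1L, 0L, 0L, 0L, 9L)),
                      method = "lilliefors")
  expect_equal(r2$verdict, "not-normal")
})

test_that("Lilliefors route agrees with the reference implementation", {
  skip_if_not_installed("nortest")
  set.seed(99)
  for (i in 1:6) {
    x <- round(rnorm(30, 40, 9))
    r <- ks_one_sample(lifespan_series(pmax(x, 0)), method = "lilliefors")
    ref <- nortest::lillie.test(as.numeric(sort(pmax(x, 0))))
    expect_equal(r$d, unname(ref$statistic), tolerance = 1e-10)
  }
  # clearly non-normal sample: both routes reject
  y <- c(rep(1, 15), rep(50, 15))
  r <- ks_one_sample(lifespan_series(y), method = "lilliefors")
  expect_equal(r$verdict, "not-normal")
  expect_lt(nortest::lillie.test(y)$p.value, 0.05)
})

test_that("survival curves are the no-censoring product limit", {
  sc <- survival_curve(lifespan_series(c(3, 3, 3)))
  expect_equal(sc$s, c(1, 1, 1, 0))
  sc2 <- survival_curve(lifespan_series(c(1, 1, 2, 2)))
  expect_equal(sc2$s[sc2$day == 1], 0.5)
  expect_equal(sc2$s[sc2$day == 2], 0)
  for (seed in 1:8) {
    d <- deaths_per_day(random_deaths_table(seed))
    sc <- survival_curve(d)
    closed <- (d$n - cumsum(d$counts)) / d$n
    expect_equal(sc$s, closed, tolerance = 1e-12)
    expect_true(all(diff(sc$s) <= 1e-12))
    expect_equal(min(sc$s), 0)
  }
})

test_that("two-sample KS on survival curves matches oracles and is symmetric", {
  a <- lifespan_series(rep(c(10, 20, 30), 10))
  expect_equal(ks_two_sample(a, a)$d, 0)
  expect_equal(ks_two_sample(a, a)$verdict, "not-different")
  expect_equal(ks_two_sample(lifespan_series(c(1, 1, 1)),
                             lifespan_series(c(10, 10, 10)))$d, 1)
  # D_crit arithmetic at n = m = 100
  b100 <- lifespan_series(rep(1:10, 10)); c100 <- lifespan_series(rep(3:12, 10))
  expect_equal(ks_two_sample(b100, c100)$d_crit, 0.19206, tolerance = 1e-4)

  for (seed in 1:10) {
    a <- as_lifespans(deaths_per_day(random_deaths_table(seed)))
    b <- as_lifespans(deaths_per_day(random_deaths_table(seed + 100)))
    r1 <- ks_two_sample(a, b); r2 <- ks_two_sample(b, a)
    expect_equal(r1$d, r2$d, tolerance = 1e-12)
    expect_gte(r1$d, 0); expect_lte(r1$d, 1)
    expect_equal(r1$d, oracle_ks2_d(as.numeric(a), as.numeric(b)), tolerance = 1e-12)
    ref <- suppressWarnings(ks.test(as.numeric(a), as.numeric(b)))
    expect_equal(r1$d, unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("one-sided two-sample p-values follow the refined and halved rules", {
  a <- lifespan_series(rep(c(5, 15, 25, 35), 25))
  b <- lifespan_series(rep(c(10, 20, 30, 40), 30))
  two <- ks_two_sample(a, b, sided = "two")
  half <- ks_two_sample(a, b, sided = "one", one_sided_rule = "half")
  refined <- ks_two_sample(a, b, sided = "one", one_sided_rule = "refined")
  expect_equal(half$p, two$p / 2, tolerance = 1e-12)
  n <- 100; m <- 120; z <- two$z
  expect_equal(refined$p,
               exp(-2 * z^2 - (2 * z / 3) * (m + 2 * n) / sqrt(m * n * (m + n))),
               tolerance = 1e-12)
})
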
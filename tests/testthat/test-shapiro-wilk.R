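test_that("W coefficients have the order-statistic structure", {
  expect_equal(sw_coefficients(3), 0.7071, tolerance = 1e-4,
               ignore_attr = TRUE)            # 1/sqrt(2) analytically
  for (n in c(4, 7, 10, 15, 20, 30, 50)) {
    a <- sw_coefficients(n)
    expect_true(all(a > 0))
    expect_true(all(diff(a) < 0))             # decreasing toward the centre
    # full antisymmetric vector: sums to 0, squares sum to 1
    full <- c(-rev(a), if (n %% 2) 0, a)
    expect_equal(sum(full), 0, tolerance = 1e-12)
    expect_equal(sum(full^2), 1, tolerance = 2e-3)
  }
  expect_identical(attr(sw_coefficients(20), "source"), "table")
  expect_identical(attr(sw_coefficients(21), "source"), "approximation")
  expect_error(sw_coefficients(2), "between 3 and 50")
  expect_error(sw_coefficients(51), "between 3 and 50")
})

test_that("W statistic: hand value, affine invariance, bounds", {
  expect_equal(as.numeric(sw_w(c(1, 2, 3))), 1, tolerance = 1e-4)  # (0.7071*2)^2/2
  expect_error(sw_w(c(4, 4, 4)), "constant")
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(sample(5:50, 1), 30, 8)
    w <- as.numeric(sw_w(x))
    expect_gt(w, 0); expect_lte(w, 1)
    expect_equal(as.numeric(sw_w(3.2 * x - 11)), w, tolerance = 1e-9)
  }
})

test_that("W agrees with the reference implementation within 0.01 on count vectors", {
  set.seed(11)
  for (i in 1:25) {
    k <- sample(5:50, 1)
    cts <- rpois(k, lambda = runif(1, 2, 40))
    if (sd(cts) == 0) next
    expect_equal(as.numeric(sw_w(cts)),
                 unname(shapiro.test(cts)$statistic),
                 tolerance = 0.011,
                 info = paste("k =", k))
  }
})

test_that("Royston's p transformation reproduces its moment curves", {
  # direct evaluation of the mu_z / sigma_z polynomials at n = 20
  ln <- log(20)
  mu_z <- 0.0038915 * ln^3 - 0.083751 * ln^2 - 0.31082 * ln - 1.5861
  sigma_z <- exp(0.0030302 * ln^2 - 0.082676 * ln - 0.4803)
  expect_equal(mu_z, -3.1642, tolerance = 1e-4)
  expect_equal(sigma_z, 0.4962, tolerance = 1e-4)
  expect_equal(royston_p(0.95, 20),
               pnorm((log(1 - 0.95) - mu_z) / sigma_z, lower.tail = FALSE),
               tolerance = 1e-12)
  # W -> 1 drives p -> 1; monotone increasing in W
  expect_gt(royston_p(0.999999, 20), 0.999)
  p <- sapply(seq(0.5, 0.99, 0.01), royston_p, n = 15)
  expect_true(all(diff(p) > 0))
  # finite, non-zero p across the W range at both ends of the n range
  for (n in c(12, 2000)) {
    p <- sapply(c(0.1, 0.5, 0.9, 0.99, 0.999), royston_p, n = n)
    expect_true(all(is.finite(p) & p > 0 & p < 1))
  }
  expect_error(royston_p(1.2, 20), "W must lie")
})

test_that("hybrid test verdicts follow p >= alpha on interval counts", {
  # near-linear sorted counts resemble normal order statistics -> normal
  f <- new_frequency_series_for_test(c(2L, 5L, 9L, 13L, 16L, 14L, 10L, 6L, 3L, 1L))
  r <- sw_test_hybrid(f, warn_small = FALSE)
  expect_equal(r$n, 10)
  expect_equal(r$verdict, "normal")

  # one dominant interval after sorting [0,0,0,1,9] -> strongly non-normal
  f2 <- new_frequency_series_for_test(c(9L, 0L, 0L, 0L, 1L))
  r2 <- sw_test_hybrid(f2, warn_small = FALSE)
  expect_equal(r2$verdict, "not-normal")
  expect_lt(r2$w, 0.7)

  # verdict flips exactly at p = alpha
  expect_equal(sw_test_hybrid(f, alpha = r$p, warn_small = FALSE)$verdict, "normal")
  expect_equal(sw_test_hybrid(f, alpha = r$p * 1.000001, warn_small = FALSE)$verdict,
               "not-normal")

  expect_warning(sw_test_hybrid(f2), "extrapolated")
  expect_error(sw_test_hybrid(new_frequency_series_for_test(c(0L, 3L, 2L))),
               "trim_zero_intervals")
})

test_that("full Royston test agrees with the reference implementation", {
  set.seed(23)
  for (n in c(20, 50, 150, 500)) {
    x <- lifespan_series(pmax(round(rnorm(n, 40, 10)), 0))
    r <- sw_test_royston(x)
    ref <- shapiro.test(as.numeric(x))
    expect_equal(r$w, unname(ref$statistic), tolerance = 1e-3)
    expect_equal(r$p, ref$p.value, tolerance = 0.02)
  }
  # calibration: normal cohorts are rarely rejected
  set.seed(31)
  verdicts <- replicate(40, {
    x <- lifespan_series(pmax(round(rnorm(200, 40, 8)), 0))
    sw_test_royston(x)$verdict
  })
  expect_gte(mean(verdicts == "normal"), 0.85)
  # strongly bimodal cohort is rejected
  bim <- lifespan_series(c(round(rnorm(100, 15, 2)), round(rnorm(100, 60, 2))))
  expect_equal(sw_test_royston(bim)$verdict, "not-normal")
  expect_error(sw_test_royston(lifespan_series(c(3, 4, 5))), "between 12 and 5000")
})
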
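test_that("Sturges width and count evaluate the rule correctly", {
  expect_equal(sturges_width(64, 128), 8)        # 1 + log2(128) = 8
  expect_equal(sturges_width(50, 16), 10)
  expect_equal(sturges_width(64, 404), 6.626, tolerance = 1e-3)
  expect_error(sturges_width(0, 10), "positive")

  expect_equal(sturges_count(128), 8L)
  expect_equal(sturges_count(404, "down"), 9L)
  expect_equal(sturges_count(404, "up"), 10L)
  # monotone non-decreasing in N for a fixed mode
  ks <- sapply(c(10, 50, 100, 500, 1000), sturges_count, rounding = "down")
  expect_true(all(diff(ks) >= 0))
  # width/count duality: rounding the width up never increases the count
  expect_lte(ceiling(70 / sturges_width(70, 300, "up")),
             ceiling(70 / sturges_width(70, 300, "down")))
})

test_that("intervalize reproduces hand counts and the unit-width identity", {
  s <- lifespan_series(c(5, 6, 6, 8, 9, 10))
  f <- intervalize(s)
  expect_equal(f$counts, c(0L, 5L, 1L))
  expect_equal(f$frequencies, c(0, 500 / 6, 100 / 6), tolerance = 1e-9)
  expect_equal(sum(f$frequencies), 100, tolerance = 1e-9)

  for (seed in 1:10) {
    d <- deaths_per_day(random_deaths_table(seed))
    f1 <- intervalize(d, width = 1)
    expect_identical(f1$counts, d$counts)   # width 1 reproduces deaths per day
  }
})

test_that("fractional and shifted binning match a boundary-scan oracle", {
  for (seed in 1:12) {
    s <- as_lifespans(deaths_per_day(random_deaths_table(seed)))
    for (w in c(3, 5, 7.17, 4.6)) for (sd0 in 0:4) {
      f <- intervalize(s, width = w, start_day = sd0)
      expect_equal(f$counts,
                   oracle_bin(as.numeric(s), w, sd0, k = f$k),
                   info = sprintf("seed %d width %g start %d", seed, w, sd0))
      expect_equal(sum(f$counts), length(s))
    }
  }
})

test_that("shifting the start day shifts every boundary by the shift", {
  s <- lifespan_series(c(7, 12, 15, 22, 30))
  f0 <- intervalize(s, width = 5, start_day = 0)
  for (sh in 1:4) {
    fs <- intervalize(s, width = 5, start_day = sh)
    expect_equal(fs$breaks[1] %% 5, sh %% 5)
    expect_equal(diff(fs$breaks), diff(f0$breaks)[seq_along(diff(fs$breaks))])
  }
})

test_that("zero-interval trimming removes only empty edge bins", {
  s <- lifespan_series(c(5, 6, 6, 8, 9, 10))
  f <- intervalize(s)                       # counts 0 5 1
  expect_equal(trim_zero_intervals(f, "leading")$counts, c(5L, 1L))
  expect_equal(trim_zero_intervals(f, "leading")$start_day, 5)

  f2 <- new_frequency_series_for_test(c(5L, 0L, 1L))
  expect_equal(trim_zero_intervals(f2, "leading")$counts, c(5L, 0L, 1L))

  f3 <- new_frequency_series_for_test(c(0L, 5L, 0L))
  expect_equal(trim_zero_intervals(f3, "both")$counts, 5L)
  # count conservation
  expect_equal(trim_zero_intervals(f3, "both")$n, f3$n)
})

test_that("display-only padding is flagged and refused by the tests", {
  f <- trim_zero_intervals(intervalize(lifespan_series(c(5, 6, 6, 8, 9, 10))))
  p3 <- pad_zero_intervals(f, 3)
  expect_equal(p3$counts, c(5L, 1L, 0L))
  expect_true(p3$display_only)
  expect_identical(pad_zero_intervals(f, f$k), f)    # no-op at current k
  expect_error(pad_zero_intervals(f, 1), "at least")
  expect_error(sw_test_hybrid(pad_zero_intervals(f, 4)), "display-only")
  expect_error(ks_one_sample(pad_zero_intervals(f, 4)), "display-only")
})

test_that("interval-count equalization gives equal k and keeps one-sided zeros", {
  set.seed(42)
  a <- fixture_cohort("normal", 300, span = 60, first_death = 5, seed = 11)
  b <- fixture_cohort("normal", 150, span = 45, first_death = 20, seed = 12)
  eq <- equalize_pair(a, b)
  expect_equal(eq$a$k, eq$b$k)
  expect_equal(eq$a$k, min(sturges_count(length(a)), sturges_count(length(b))))
  expect_equal(sum(eq$a$counts), length(a))
  expect_equal(sum(eq$b$counts), length(b))
  # b starts at day 20: its leading intervals are empty but a's are not,
  # so they must be kept in both
  expect_true(any(eq$b$counts == 0) || min(b) < eq$b$width)
  expect_equal(eq$a$start_day, eq$b$start_day)

  # identical samples give identical schemes and counts
  eq2 <- equalize_pair(a, a)
  expect_identical(eq2$a$counts, eq2$b$counts)
  expect_equal(eq2$a$width, eq2$b$width)

  # leading intervals empty in BOTH are dropped
  c1 <- fixture_cohort("normal", 200, span = 30, first_death = 40, seed = 13)
  c2 <- fixture_cohort("normal", 200, span = 30, first_death = 45, seed = 14)
  eq3 <- equalize_pair(c1, c2)
  expect_true(eq3$a$counts[1] > 0 || eq3$b$counts[1] > 0)
})
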
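test_that("build_index averages member regions per year", {
  period <- study_period(1700, 1704)
  climate <- list(
    a = climate_series("a", 1700, rep(1, 5)),
    b = climate_series("b", 1700, rep(3, 5)),
    c = climate_series("c", 1700, c(1, 2, 3, 4, 5))
  )
  expect_equal(build_index(climate, "a", period = period)$values, rep(1, 5))
  expect_equal(build_index(climate, c("a", "b"), period = period)$values,
               rep(2, 5))
  expect_equal(build_index(climate, c("a", "b", "c"), period = period)$values,
               (rep(1, 5) + rep(3, 5) + 1:5) / 3)
  expect_error(build_index(climate, character(0)), "non-empty")
  expect_error(build_index(climate, "zzz"), "unknown region")
})

test_that("anomalies subtract the full-period mean", {
  period <- study_period(1700, 1709)
  const <- climate_series("i", 1700, rep(2.5, 10))
  expect_equal(compute_anomalies(const, period)$values, rep(0, 10))
  centered <- climate_series("i", 1700, c(-2, -1, 0, 1, 2, -2, -1, 0, 1, 2))
  expect_equal(compute_anomalies(centered, period)$values, centered$values)
  ramp <- compute_anomalies(climate_series("i", 1700, 1:10), period)
  expect_equal(ramp$values, rev(-ramp$values))
})

test_that("sea composites events and flags only real anomalies", {
  period <- study_period(1700, 1799)
  # constant index: all composites zero, nothing significant
  anom <- compute_anomalies(climate_series("i", 1700, rep(1.3, 100)), period)
  s <- sea(anom, c(1725, 1760), period, n_boot = 200, seed = 1)
  expect_equal(s$table$composite, rep(0, 11))
  expect_false(any(s$table$significant))

  # delta spike: the composite reproduces the shifted spike
  vals <- rep(0, 100)
  vals[51] <- 5  # year 1750
  spike <- climate_series("i", 1700, vals)
  anom <- compute_anomalies(spike, period)
  s <- sea(anom, 1752, period, n_boot = 50, seed = 1)
  expect_equal(s$table$composite[s$table$lag == -2], 5 - 0.05)
  expect_equal(s$table$composite[s$table$lag == 0], -0.05)

  expect_error(sea(anom, integer(0), period), "no events")
  expect_error(sea(anom, 1650, period), "outside the study period")
})

test_that("sea is seed-reproducible and boundary events truncate or drop", {
  period <- study_period(1700, 1799)
  set.seed(6)
  anom <- compute_anomalies(climate_series("i", 1700, rnorm(100)), period)
  s1 <- sea(anom, c(1702, 1750), period, n_boot = 100, seed = 9)
  s2 <- sea(anom, c(1702, 1750), period, n_boot = 100, seed = 9)
  expect_identical(s1, s2)
  s3 <- sea(anom, c(1702, 1750), period, n_boot = 100, seed = 9,
            drop_boundary_events = TRUE)
  expect_identical(s3$n_events, 1L)
})

test_that("pre_event_years unions clipped pre-start windows", {
  period <- study_period(1700, 1990)
  p <- data.frame(start = 1715)
  expect_equal(pre_event_years(p, period), 1710:1714)
  expect_length(pre_event_years(data.frame(start = 1700), period), 0L)
  overlap <- data.frame(start = c(1715, 1717))
  expect_equal(pre_event_years(overlap, period), 1710:1716)
  expect_equal(pre_event_years(data.frame(start = 1703), period, k = 5),
               1700:1702)
})

test_that("welch_t matches the textbook formula and stats::t.test", {
  expect_equal(welch_t(c(1, 1, 1), c(1, 1, 1))[c("t", "p")],
               list(t = 0, p = 1))
  sep <- welch_t(c(0, 0, 0, 0) + rnorm(4, 0, 1e-8), c(1, 1, 1, 1))
  expect_gt(abs(sep$t), 1e4)
  expect_lt(sep$p, 1e-6)

  set.seed(10)
  for (i in 1:10) {
    a <- rnorm(sample(3:30, 1))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    got <- welch_t(a, b)
    want <- oracle_welch(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("group_comparisons contrasts period and pre-event years", {
  period <- study_period(1700, 1749)
  periods <- data.frame(start = c(1710, 1730), end = c(1715, 1734))
  const <- climate_series("i", 1700, rep(1, 50))
  gc <- group_comparisons(const, periods, period)
  expect_equal(gc$t, c(0, 0))
  expect_equal(gc$n1[1], 11)  # 6 + 5 period years
  expect_equal(gc$n1[2], 10)  # two disjoint 5-year pre windows

  # forced pattern: drier before starts, wetter inside periods
  vals <- rep(0, 50)
  yrs <- 1700:1749
  vals[yrs %in% c(1705:1709, 1725:1729)] <- -2
  vals[yrs %in% c(1710:1715, 1730:1734)] <- 2
  forced <- climate_series("i", 1700, vals + rnorm(50, 0, 0.1))
  gc <- group_comparisons(forced, periods, period)
  expect_gt(gc$t[gc$contrast == "synchronous_vs_other"], 0)
  expect_lt(gc$t[gc$contrast == "pre_event_vs_other"], 0)
  expect_lt(gc$p[1], 0.01)

  all_years <- data.frame(start = 1700, end = 1749)
  expect_error(group_comparisons(const, all_years, period), "empty group")
})
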
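test_that("events_from_record extracts the three event types", {
  period <- study_period(1700, 1990)
  s <- binary_series("x", 1700, as.numeric(1700:1990 %in% 1715:1733))
  expect_equal(events_from_record(s, "initiations", period)$years, 1715L)
  expect_equal(events_from_record(s, "cessations", period)$years, 1733L)
  expect_equal(events_from_record(s, "outbreak_years", period)$years,
               1715:1733)

  zero <- binary_series("z", 1700, rep(0, 291))
  expect_length(events_from_record(zero, "outbreak_years", period)$years, 0L)

  two <- binary_series("y", 1700,
                       as.numeric(1700:1990 %in% c(1710:1712, 1800:1805)))
  expect_equal(events_from_record(two, "initiations", period)$years,
               c(1710L, 1800L))
  expect_equal(events_from_record(two, "cessations", period)$years,
               c(1712L, 1805L))
})

test_that("cross_k matches hand-computed single-event cases", {
  period <- study_period(1700, 1990)  # n = 291
  k <- cross_k(1750L, 1750L, t_max = 5, period = period)
  expect_equal(unname(k), rep(291, 6))

  k <- cross_k(1750L, 1760L, t_max = 15, period = period)
  expect_equal(unname(k[as.character(0:9)]), rep(0, 10))
  expect_equal(unname(k[as.character(10:15)]), rep(291, 6))

  # b everywhere: K(t) equals the mean symmetric window occupancy
  a <- c(1705L, 1800L)
  b <- 1700:1990
  k <- cross_k(a, b, t_max = 3, period = period)
  expect_equal(unname(k), oracle_cross_k(a, b, 3, 291))

  expect_error(cross_k(integer(0), 1750L, 5, period), "empty")
})

test_that("cross_k is symmetric, non-decreasing, and equals the oracle", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(50:300, 1)
    period <- study_period(1700, 1700 + n - 1)
    a <- sort(sample(period$start_year:period$end_year, sample(1:20, 1)))
    b <- sort(sample(period$start_year:period$end_year, sample(1:20, 1)))
    t_max <- sample(0:25, 1)
    k_ab <- cross_k(a, b, t_max, period)
    expect_equal(unname(k_ab), oracle_cross_k(a, b, t_max, n))
    expect_equal(k_ab, cross_k(b, a, t_max, period))
    expect_true(all(diff(k_ab) >= 0))
  }
})

test_that("multivariate_k pools pairs and equals the triple-loop oracle", {
  period <- study_period(1700, 1990)
  # identical single-event series: K(0) attains its maximum n; with m events
  # per region the pooled estimator gives n/m (m same-year pairs out of m^2)
  single <- replicate(7, 1750L, simplify = FALSE)
  expect_equal(unname(multivariate_k(single, 2, period)[1]), 291)
  same <- replicate(7, c(1710L, 1750L, 1800L), simplify = FALSE)
  k <- multivariate_k(same, t_max = 2, period = period)
  expect_equal(unname(k[1]), 291 / 3)

  # pairwise distant events: zero at small windows
  apart <- list(1710L, 1810L, 1910L)
  expect_equal(unname(multivariate_k(apart, 25, period)), rep(0, 26))

  set.seed(33)
  for (i in 1:10) {
    n <- sample(40:150, 1)
    period_i <- study_period(1800, 1800 + n - 1)
    series <- lapply(seq_len(sample(2:5, 1)), function(j) {
      sort(sample(period_i$start_year:period_i$end_year, sample(1:12, 1)))
    })
    t_max <- sample(0:20, 1)
    expect_equal(unname(multivariate_k(series, t_max, period_i)),
                 oracle_multivariate_k(series, t_max, n))
  }
  expect_error(multivariate_k(list(integer(0), integer(0)), 5, period),
               "non-empty")
})

test_that("l_transform centres the discrete-window independence expectation", {
  expect_equal(unname(l_transform(c(`0` = 1))), 0)
  expect_equal(unname(l_transform(c(`0` = 291))), 145)
  k <- c(`0` = 1, `1` = 3, `2` = 5, `3` = 7, `4` = 9, `5` = 11)
  expect_equal(unname(l_transform(k)), rep(0, 6))
})

test_that("rotation preserves totals and a full-cycle rotation is identity", {
  set.seed(5)
  for (i in 1:15) {
    s <- random_binary("r", 1700, sample(20:100, 1))
    n <- length(s$values)
    expect_equal(rotate_series(s, n)$values, s$values)
    off <- sample(n - 1, 1)
    rot <- rotate_series(s, off)
    expect_equal(sum(rot$values), sum(s$values))
    # durations multiset is preserved up to one episode split at the seam
    d0 <- sort(extract_episodes(s)$duration)
    d1 <- sort(extract_episodes(rot)$duration)
    expect_lte(abs(length(d1) - length(d0)), 1L)
    expect_equal(sum(d1), sum(d0))
    # rotating back restores the record
    expect_equal(rotate_series(rot, n - off)$values, s$values)
  }
})

test_that("circular envelope is seed-reproducible and detects duplication", {
  set.seed(17)
  base <- random_binary("a", 1700, 120, 0.25)
  records <- list(a = base, b = binary_series("b", 1700, base$values),
                  c = random_binary("c", 1700, 120, 0.25))
  period <- study_period(1700, 1819)
  e1 <- circular_envelope(records, "outbreak_years", period, t_max = 10,
                          n_sim = 99, seed = 123)
  e2 <- circular_envelope(records, "outbreak_years", period, t_max = 10,
                          n_sim = 99, seed = 123)
  expect_identical(e1$table, e2$table)
  # two identical regions force same-year clustering above the envelope
  expect_gt(e1$table$L[1], e1$table$env_high[1])
  expect_true(all(e1$table$env_low <= e1$table$env_high))
})
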
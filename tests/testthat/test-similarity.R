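test_that("outbreak similarity counts agreement years", {
  period <- study_period(1700, 1709)
  x <- binary_series("x", 1700, c(1, 1, 0, 0, 1, 0, 0, 1, 0, 0))
  y <- binary_series("y", 1700, c(1, 0, 0, 0, 1, 1, 0, 1, 0, 1))
  ct <- pair_agreement(x, y, period)
  expect_equal(ct, list(a = 3L, b = 4L, c = 1L, d = 2L))
  expect_equal(outbreak_similarity(x, y, period), 0.7)

  expect_equal(outbreak_similarity(x, x, period), 1)
  comp <- binary_series("c", 1700, 1 - x$values)
  expect_equal(outbreak_similarity(x, comp, period), 0)

  # symmetry and invariance under joint 0/1 relabeling
  expect_equal(outbreak_similarity(y, x, period),
               outbreak_similarity(x, y, period))
  xr <- binary_series("xr", 1700, 1 - x$values)
  yr <- binary_series("yr", 1700, 1 - y$values)
  expect_equal(outbreak_similarity(xr, yr, period),
               outbreak_similarity(x, y, period))
})

test_that("climate similarity is minus the mean absolute difference", {
  period <- study_period(1700, 1701)
  expect_equal(climate_similarity(climate_series("a", 1700, c(0, 2)),
                                  climate_series("b", 1700, c(1, 0)),
                                  period), -1.5)
  a <- climate_series("a", 1700, c(0.3, -1.2))
  expect_equal(climate_similarity(a, a, period), 0)
  b <- climate_series("b", 1700, a$values + 1)
  expect_equal(climate_similarity(a, b, period), -1)
  set.seed(2)
  for (i in 1:10) {
    p <- study_period(1700, 1749)
    u <- climate_series("u", 1700, rnorm(50))
    v <- climate_series("v", 1700, rnorm(50))
    expect_lte(climate_similarity(u, v, p), 0)
  }
})

test_that("centroid distances are planar Euclidean", {
  regions <- data.frame(region_id = c("p", "q"), east_km = c(0, 3),
                        north_km = c(0, 4))
  d <- centroid_distances(regions)
  expect_equal(d["p", "q"], 5)
  expect_true(is.na(d["p", "p"]))

  dup <- data.frame(region_id = c("p", "q"), east_km = 0, north_km = 0)
  expect_warning(centroid_distances(dup), "identical centroid")

  set.seed(4)
  pts <- data.frame(region_id = paste0("r", 1:7),
                    east_km = runif(7, 0, 500), north_km = runif(7, 0, 2000))
  d <- centroid_distances(pts)
  for (i in 1:6) for (j in (i + 1):7) {
    expect_equal(d[i, j], sqrt((pts$east_km[i] - pts$east_km[j])^2 +
                                 (pts$north_km[i] - pts$north_km[j])^2))
  }
})

test_that("distance-decay regression matches closed-form OLS", {
  ids <- paste0("r", 1:5)
  set.seed(8)
  dmat <- random_pairwise(5, ids) * 1000
  # perfectly collinear: R^2 = 1
  sim <- -0.0002 * dmat + 0.9
  diag(sim) <- NA_real_
  fit <- distance_decay_regression(sim, dmat)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, -0.0002)
  expect_equal(fit$intercept, 0.9)

  # constant similarity: nothing to explain
  const <- dmat * 0 + 0.5
  diag(const) <- NA_real_
  expect_equal(distance_decay_regression(const, dmat)$r_squared, 0)

  # noisy case against the closed-form slope/intercept
  noisy <- sim
  noisy[upper.tri(noisy)] <- noisy[upper.tri(noisy)] + rnorm(10, 0, 0.05)
  noisy[lower.tri(noisy)] <- t(noisy)[lower.tri(noisy)]
  fit <- distance_decay_regression(noisy, dmat)
  x <- dmat[upper.tri(dmat)]
  y <- noisy[upper.tri(noisy)]
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit$slope, slope)
  expect_equal(fit$intercept, mean(y) - slope * mean(x))
  expect_equal(fit$r_squared, cor(x, y)^2)
})

test_that("mantel r matches trivial cases and the vegan statistic", {
  set.seed(12)
  a <- random_pairwise(6)
  expect_equal(mantel_test(a, a, n_perm = 50, seed = 1)$r, 1)
  neg <- -a
  expect_equal(mantel_test(a, neg, n_perm = 50, seed = 1)$r, -1)

  b <- random_pairwise(6)
  r_ours <- mantel_test(a, b, n_perm = 10, seed = 1)$r
  skip_if_not_installed("vegan")
  a0 <- a; b0 <- b
  diag(a0) <- 0; diag(b0) <- 0
  r_vegan <- vegan::mantel(as.dist(a0), as.dist(b0), permutations = 5)$statistic
  expect_equal(r_ours, unname(r_vegan), tolerance = 1e-12)
})

test_that("mantel r is invariant under a common region re-ordering", {
  set.seed(13)
  a <- random_pairwise(7)
  b <- random_pairwise(7)
  r0 <- mantel_test(a, b, n_perm = 5, seed = 1)$r
  idx <- sample(7)
  r1 <- mantel_test(a[idx, idx], b[idx, idx], n_perm = 5, seed = 1)$r
  expect_equal(r1, r0)
})

test_that("mantel permutation p agrees with exhaustive enumeration", {
  set.seed(14)
  for (i in 1:3) {
    a <- random_pairwise(4)
    b <- random_pairwise(4)
    exact <- oracle_mantel_exact_p(a, b)
    mc <- mantel_test(a, b, n_perm = 4000, seed = i)
    expect_equal(mc$r, exact$r)
    tol <- 4 * sqrt(exact$p * (1 - exact$p) / 4000) + 2 / 4000
    expect_lt(abs(mc$p - exact$p), tol + 1e-12)
    expect_gte(mc$p, 1 / (mc$n_perm + 1))
    expect_lte(mc$p, 1)
  }
})

test_that("partial mantel residualizes correctly", {
  set.seed(15)
  a <- random_pairwise(8)
  b <- random_pairwise(8)
  c0 <- random_pairwise(8)
  # b fully explained by the conditioning matrix: r collapses to 0
  expect_warning(res <- partial_mantel_test(a, b, b, n_perm = 50, seed = 1),
                 "fully explained")
  expect_lt(abs(res$r), 1e-10)

  # conditioning on an unrelated matrix barely changes r (simulation check)
  diffs <- replicate(30, {
    a <- random_pairwise(10)
    b_half <- a
    b_half[upper.tri(b_half)] <- 0.7 * a[upper.tri(a)] + 0.3 * runif(45)
    b_half[lower.tri(b_half)] <- t(b_half)[lower.tri(b_half)]
    c_ind <- random_pairwise(10)
    r_simple <- mantel_test(a, b_half, n_perm = 1, seed = 1)$r
    r_partial <- partial_mantel_test(a, b_half, c_ind, n_perm = 1, seed = 1)$r
    r_partial - r_simple
  })
  expect_lt(mean(abs(diffs)), 0.05)

  # exhaustive 4-region p
  for (i in 1:2) {
    a <- random_pairwise(4)
    b <- random_pairwise(4)
    cc <- random_pairwise(4)
    exact <- oracle_partial_mantel_exact_p(a, b, cc)
    mc <- partial_mantel_test(a, b, cc, n_perm = 4000, seed = i)
    expect_equal(mc$r, exact$r)
    tol <- 4 * sqrt(exact$p * (1 - exact$p) / 4000) + 2 / 4000
    expect_lt(abs(mc$p - exact$p), tol + 1e-12)
  }
})
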
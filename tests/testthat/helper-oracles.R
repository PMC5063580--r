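# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can vouch for the fast implementations.

# K for two event-year vectors by direct double loop over all pairs
oracle_cross_k <- function(a, b, t_max, n) {
  k <- numeric(t_max + 1)
  for (t in 0:t_max) {
    cnt <- 0
    for (u in a) for (v in b) if (abs(u - v) <= t) cnt <- cnt + 1
    k[t + 1] <- n * cnt / (length(a) * length(b))
  }
  k
}

# pooled K over all ordered cross-region pairs by triple loop
oracle_multivariate_k <- function(series_list, t_max, n) {
  k <- numeric(t_max + 1)
  denom <- 0
  for (i in seq_along(series_list)) {
    for (j in seq_along(series_list)) {
      if (i != j) denom <- denom +
          length(series_list[[i]]) * length(series_list[[j]])
    }
  }
  for (t in 0:t_max) {
    cnt <- 0
    for (i in seq_along(series_list)) {
      for (j in seq_along(series_list)) {
        if (i == j) next
        for (u in series_list[[i]]) for (v in series_list[[j]]) {
          if (abs(u - v) <= t) cnt <- cnt + 1
        }
      }
    }
    k[t + 1] <- n * cnt / denom
  }
  k
}

# Welch statistic straight from the textbook formulas
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = pos - 1)
    }
  }
  out
}

# exact two-tailed Mantel p by enumeration of all relabelings of b
oracle_mantel_exact_p <- function(a, b) {
  va <- a[upper.tri(a)]
  r_obs <- cor(va, b[upper.tri(b)])
  perms <- all_perms(nrow(a))
  rs <- vapply(perms, function(idx) {
    bp <- b[idx, idx]
    cor(va, bp[upper.tri(bp)])
  }, numeric(1))
  list(r = r_obs, p = mean(abs(rs) >= abs(r_obs) - 1e-12))
}

# exact two-tailed partial Mantel p: residualize on c, enumerate relabelings
# of the residualized a matrix
oracle_partial_mantel_exact_p <- function(a, b, c) {
  va <- a[upper.tri(a)]
  vb <- b[upper.tri(b)]
  vc <- c[upper.tri(c)]
  ra_v <- residuals(lm(va ~ vc))
  rb_v <- residuals(lm(vb ~ vc))
  ra <- matrix(0, nrow(a), ncol(a))
  ra[upper.tri(ra)] <- ra_v
  ra <- ra + t(ra)
  r_obs <- cor(ra_v, rb_v)
  rs <- vapply(all_perms(nrow(a)), function(idx) {
    rp <- ra[idx, idx]
    cor(rp[upper.tri(rp)], rb_v)
  }, numeric(1))
  list(r = r_obs, p = mean(abs(rs) >= abs(r_obs) - 1e-12))
}

# random symmetric pairwise matrix with NA diagonal
random_pairwise <- function(n, ids = paste0("r", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- runif(n * (n - 1) / 2)
  m <- m + t(m)
  diag(m) <- NA_real_
  m
}

random_binary <- function(id, first_year, n, p = 0.3) {
  binary_series(id, first_year, rbinom(n, 1, p))
}

# small scenario used by pipeline/synthetic tests to keep runtimes low
small_scenario <- function(beta = 0, n_years = 120L, ...) {
  regions <- data.frame(region_id = c("N1", "N2", "N3", "S1"),
                        east_km = 0, north_km = c(900, 600, 300, 0))
  scenario_config(regions, n_years = n_years, first_year = 1800L,
                  groups = c("northwest", "northwest", "northwest",
                             "southwest"),
                  mean_duration = 10, mean_quiescent = 12, beta = beta, ...)
}
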
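#' Extract discrete outbreak events from a binary record
#'
#' Three event types are supported: every outbreak year, episode initiation
#' years (first year of each maximal run of 1s) and episode cessation years
#' (last year of each run).
#'
#' @param series A [binary_series()] covering `period`.
#' @param event_type One of `"outbreak_years"`, `"initiations"`,
#'   `"cessations"`.
#' @param period A [study_period()].
#' @return An object of class `event_series`: list with `region_id`,
#'   `event_type` and sorted integer `years`.
#' @examples
#' s <- binary_series("x", 1700, c(0, 1, 1, 1, 0))
#' events_from_record(s, "initiations", study_period(1700, 1704))$years # 1701
#' @export
events_from_record <- function(series,
                               event_type = c("outbreak_years", "initiations",
                                              "cessations"),
                               period) {
  event_type <- match.arg(event_type)
  ep <- extract_episodes(series, period)
  years <- switch(event_type,
    outbreak_years = {
      x <- series_window(series, period)
      period_years(period)[x == 1]
    },
    initiations = ep$start,
    cessations = ep$end
  )
  structure(
    list(region_id = series$region_id, event_type = event_type,
         years = as.integer(years)),
    class = "event_series"
  )
}

#' @export
print.event_series <- function(x, ...) {
  cat("event_series '", x$region_id, "' (", x$event_type, "): ",
      length(x$years), " events\n", sep = "")
  invisible(x)
}

event_years <- function(e) if (inherits(e, "event_series")) e$years else
  as.integer(e)

#' Bivariate one-dimensional Ripley's K
#'
#' Counts, for each temporal window half-width `t = 0..t_max`, the ordered
#' event pairs (one event from each series) that fall within `t` years of
#' each other, normalized by record length and event counts:
#' `K(t) = n / (n_a * n_b) * sum_{u in a} #\{v in b : |u - v| <= t\}`.
#' Windows are symmetric and inclusive, so `t = 0` counts same-year
#' co-occurrence. No analytic edge correction is applied: significance in
#' this package is always judged against circular-shift randomizations that
#' share the finite-window bias (see [circular_envelope()]).
#'
#' @param a,b `event_series` objects (or plain integer year vectors).
#' @param t_max Largest window half-width in years; must be `< period$n`.
#' @param period A [study_period()] supplying the record length `n`.
#' @return Numeric vector of length `t_max + 1`, names `"0".."t_max"`.
#' @export
cross_k <- function(a, b, t_max, period) {
  ya <- event_years(a)
  yb <- event_years(b)
  if (length(ya) == 0L) stop("event series 'a' is empty")
  if (length(yb) == 0L) stop("event series 'b' is empty")
  stopifnot(t_max >= 0L, t_max < period$n)
  d <- abs(outer(ya, yb, "-"))
  # histogram of |u - v| clipped beyond t_max, then cumulative counts
  counts <- cumsum(tabulate(pmin(d, t_max + 1L) + 1L, nbins = t_max + 1L))
  k <- period$n * counts / (length(ya) * length(yb))
  names(k) <- 0:t_max
  k
}

# Pooled pair counts for >= 2 regions via per-year indicators and windowed
# cumulative sums: O((R + 1) * t_max * n) instead of enumerating pairs.
pooled_k_from_indicators <- function(ind, t_max) {
  n <- nrow(ind)
  nev <- colSums(ind)
  denom <- sum(nev)^2 - sum(nev^2)  # ordered cross pairs
  if (denom <= 0) stop("fewer than two non-empty event series")
  s <- rowSums(ind)
  C0s <- c(0, cumsum(s))
  C0i <- rbind(0, apply(ind, 2L, cumsum))
  u <- seq_len(n)
  k <- numeric(t_max + 1L)
  for (t in 0:t_max) {
    hi <- pmin(u + t, n) + 1L
    lo <- pmax(u - t - 1L, 0L) + 1L
    total <- sum(s * (C0s[hi] - C0s[lo]))
    self <- sum(ind * (C0i[hi, , drop = FALSE] - C0i[lo, , drop = FALSE]))
    k[t + 1L] <- n * (total - self) / denom
  }
  names(k) <- 0:t_max
  k
}

events_to_indicators <- function(series_list, period) {
  ind <- matrix(0, nrow = period$n, ncol = length(series_list))
  yrs <- period$start_year
  for (j in seq_along(series_list)) {
    y <- event_years(series_list[[j]])
    if (any(y < period$start_year | y > period$end_year)) {
      stop("events outside the study period in series ", j)
    }
    ind[y - yrs + 1L, j] <- 1
  }
  ind
}

#' Pooled multivariate one-dimensional Ripley's K
#'
#' Pooled co-occurrence statistic across all ordered pairs of regions:
#' `K(t) = n * (cross-pair count within t) / sum_{i != j} n_i n_j`. Agrees
#' with a brute-force enumeration of all cross-region event pairs; series
#' with no events contribute nothing (at least two non-empty series are
#' required).
#'
#' @param series_list List of `event_series` (or integer year vectors).
#' @inheritParams cross_k
#' @return Numeric vector of length `t_max + 1`.
#' @export
multivariate_k <- function(series_list, t_max, period) {
  stopifnot(length(series_list) >= 2L, t_max >= 0L, t_max < period$n)
  ind <- events_to_indicators(series_list, period)
  if (sum(colSums(ind) > 0) < 2L) {
    stop("multivariate K requires at least two non-empty event series")
  }
  pooled_k_from_indicators(ind, t_max)
}

#' L-transform of a discrete-window K statistic
#'
#' Centres and rescales K so that independence has expectation approximately
#' zero at every window: a symmetric inclusive window of half-width `t` spans
#' `2t + 1` years, and for independent series `E[K(t)]` is approximately
#' `2t + 1`, so `L(t) = (K(t) - (2t + 1)) / 2`. Values above zero indicate
#' synchrony, below zero asynchrony. Any affine transform applied identically
#' to observed and randomized K leaves envelope-based significance unchanged.
#'
#' @param k Numeric vector of K values for windows `t = 0..t_max` (as
#'   returned by [cross_k()] or [multivariate_k()]).
#' @return Numeric vector of L values, same length and names.
#' @export
l_transform <- function(k) {
  t <- seq_along(k) - 1L
  out <- (k - (2 * t + 1)) / 2
  names(out) <- names(k)
  out
}

#' Circularly rotate a binary record
#'
#' Shifts the whole record forward by `offset` years with wraparound: the
#' value of year `y` moves to year `y + offset` (modulo the record length).
#' Rotation preserves within-region temporal structure (episode durations, up
#' to one episode possibly split across the wrap seam) while destroying
#' cross-region alignment.
#'
#' @param series A [binary_series()].
#' @param offset Integer shift in years.
#' @return The rotated [binary_series()].
#' @export
rotate_series <- function(series, offset) {
  n <- length(series$values)
  idx <- ((seq_len(n) - 1L - offset) %% n) + 1L
  binary_series(series$region_id, series$first_year, series$values[idx])
}

#' Circular-shift randomization envelope for the pooled K/L statistic
#'
#' Computes the observed pooled L across all regions, then `n_sim`
#' randomizations in which each region's full binary record is independently
#' rotated by a uniform offset in `1..n-1` (wraparound; offset 0 is excluded
#' so every simulation differs from the observed arrangement). Events are
#' re-extracted from each rotated record, so the within-region multi-decadal
#' structure is retained while cross-region alignment is randomized. The
#' envelope is the per-window empirical (`alpha/2`, `1 - alpha/2`) percentile
#' band of the simulated L values; observed L strictly outside the band is
#' flagged significant.
#'
#' @param records Named list of [binary_series()] covering `period`.
#' @param event_type Event type passed to [events_from_record()].
#' @param period A [study_period()].
#' @param t_max Largest window half-width (default 25 years).
#' @param n_sim Number of randomizations (default 1000).
#' @param alpha Two-sided envelope level (default 0.05).
#' @param seed Integer seed; required for reproducibility.
#' @return Object of class `ripley_envelope`: list with a `table` data.frame
#'   (`t`, `K`, `L`, `env_low`, `env_high`, `significant`) and fields
#'   `event_type`, `n_sim`, `alpha`, `period`.
#' @export
circular_envelope <- function(records,
                              event_type = c("outbreak_years", "initiations",
                                             "cessations"),
                              period, t_max = 25L, n_sim = 1000L,
                              alpha = 0.05, seed = NULL) {
  event_type <- match.arg(event_type)
  stopifnot(n_sim >= 1L, alpha > 0, alpha < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- period$n
  nr <- length(records)
  mats <- vapply(records, series_window, numeric(n), period = period)
  extract <- function(col) {
    # event years (1-based within period) from a 0/1 vector
    if (event_type == "outbreak_years") return(which(col == 1))
    r <- rle(col)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    if (event_type == "initiations") starts[r$values == 1]
    else ends[r$values == 1]
  }
  k_of <- function(m) {
    ind <- matrix(0, nrow = n, ncol = nr)
    for (j in seq_len(nr)) ind[extract(m[, j]), j] <- 1
    pooled_k_from_indicators(ind, t_max)
  }
  k_obs <- k_of(mats)
  l_obs <- l_transform(k_obs)
  sims <- matrix(NA_real_, nrow = n_sim, ncol = t_max + 1L)
  for (i in seq_len(n_sim)) {
    offs <- sample.int(n - 1L, nr, replace = TRUE)
    rot <- mats
    for (j in seq_len(nr)) {
      idx <- ((seq_len(n) - 1L - offs[j]) %% n) + 1L
      rot[, j] <- mats[idx, j]
    }
    sims[i, ] <- l_transform(k_of(rot))
  }
  # order-statistic envelope: for continuous exchangeable statistics the
  # probability of the observed value falling strictly outside
  # [x_(lo), x_(hi)] is (lo + n_sim + 1 - hi) / (n_sim + 1), i.e. exactly
  # alpha at lo = floor(alpha/2 * (n_sim+1)), hi = ceiling((1-alpha/2) *
  # (n_sim+1))
  lo_idx <- max(1L, floor(alpha / 2 * (n_sim + 1L)))
  hi_idx <- min(n_sim, ceiling((1 - alpha / 2) * (n_sim + 1L)))
  env <- apply(sims, 2L, function(x) sort(x)[c(lo_idx, hi_idx)])
  tab <- data.frame(
    t = 0:t_max,
    K = unname(k_obs),
    L = unname(l_obs),
    env_low = env[1L, ],
    env_high = env[2L, ],
    significant = unname(l_obs) < env[1L, ] | unname(l_obs) > env[2L, ]
  )
  structure(
    list(table = tab, event_type = event_type, n_sim = n_sim, alpha = alpha,
         period = period),
    class = "ripley_envelope"
  )
}

#' @export
print.ripley_envelope <- function(x, ...) {
  cat("circular-shift K/L envelope (", x$event_type, ", ", x$n_sim,
      " sims, alpha = ", x$alpha, ")\n", sep = "")
  sig <- x$table$t[x$table$significant]
  cat("significant windows:",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}
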
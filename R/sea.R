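#' Average several regional climate series into one index
#'
#' Unweighted per-year mean across member regions, e.g. an all-region PDSI
#' index, a "northwest" index over the five northwestern regions or a
#' "southwest" index over Colorado and New Mexico.
#'
#' @param climate Named list of [climate_series()].
#' @param members Character vector of region ids to average (must be a
#'   non-empty subset of `names(climate)`).
#' @param label Label for the resulting index series.
#' @param period Optional [study_period()]; defaults to the members' common
#'   period.
#' @return A [climate_series()] whose `region_id` is `label`.
#' @export
build_index <- function(climate, members, label = paste(members,
                                                        collapse = "+"),
                        period = NULL) {
  if (length(members) == 0L) stop("members must be non-empty")
  missing <- setdiff(members, names(climate))
  if (length(missing)) {
    stop("unknown regions: ", paste(missing, collapse = ", "))
  }
  sel <- climate[members]
  if (is.null(period)) period <- common_period(sel)
  vals <- rowMeans(vapply(sel, series_window, numeric(period$n),
                          period = period))
  climate_series(label, period$start_year, vals)
}

#' Anomalies of a climate index relative to its long-term mean
#'
#' Subtracts the full common-period mean from every year; no detrending or
#' windowed baseline is applied.
#'
#' @param index A [climate_series()].
#' @param period A [study_period()] the index covers.
#' @return A [climate_series()] of anomalies over `period`.
#' @export
compute_anomalies <- function(index, period) {
  vals <- series_window(index, period)
  climate_series(index$region_id, period$start_year, vals - mean(vals))
}

#' Superposed epoch analysis
#'
#' Composites a climate-anomaly series across a set of event years at fixed
#' lags (default an 11-year window, the event year plus the five years before
#' and after). The composite at lag `l` is the mean anomaly over
#' `event + l`, averaging only lags that fall inside the study period (events
#' near the boundary contribute their in-period lags; set
#' `drop_boundary_events = TRUE` to instead drop any event whose full lag
#' window leaves the period). Significance is assessed against `n_boot`
#' Monte-Carlo draws of `length(events)` years sampled uniformly without
#' replacement from all period years and composited identically; a lag is
#' flagged where the observed composite falls strictly outside the empirical
#' (`alpha/2`, `1 - alpha/2`) percentile band.
#'
#' @param anomalies A [climate_series()] of anomalies (see
#'   [compute_anomalies()]) covering `period`.
#' @param events Integer vector of event years inside `period`.
#' @param period A [study_period()].
#' @param lags Integer vector of lags (default `-5:5`).
#' @param n_boot Number of Monte-Carlo draws (default 1000).
#' @param alpha Two-sided level (default 0.05).
#' @param seed Optional integer seed.
#' @param drop_boundary_events Drop events whose lag window crosses the
#'   period boundary instead of truncating it (default `FALSE`).
#' @return Object of class `sea_composite`: list with a `table` data.frame
#'   (`lag`, `composite`, `ci_low`, `ci_high`, `significant`) plus
#'   `n_events`, `n_boot`, `alpha`.
#' @export
sea <- function(anomalies, events, period, lags = -5:5, n_boot = 1000L,
                alpha = 0.05, seed = NULL, drop_boundary_events = FALSE) {
  events <- as.integer(events)
  if (length(events) == 0L) stop("no events supplied")
  if (any(events < period$start_year | events > period$end_year)) {
    stop("events outside the study period")
  }
  vals <- series_window(anomalies, period)
  if (!is.null(seed)) set.seed(seed)
  if (drop_boundary_events) {
    keep <- events + min(lags) >= period$start_year &
      events + max(lags) <= period$end_year
    if (!any(keep)) stop("all events dropped at the period boundary")
    events <- events[keep]
  }
  composite_of <- function(ev) {
    vapply(lags, function(l) {
      idx <- ev + l - period$start_year + 1L
      idx <- idx[idx >= 1L & idx <= period$n]
      if (length(idx) == 0L) NA_real_ else mean(vals[idx])
    }, numeric(1))
  }
  obs <- composite_of(events)
  boots <- matrix(NA_real_, nrow = n_boot, ncol = length(lags))
  yrs <- period_years(period)
  for (i in seq_len(n_boot)) {
    boots[i, ] <- composite_of(sample(yrs, length(events), replace = FALSE))
  }
  # order-statistic band, same rank convention as circular_envelope()
  lo_idx <- max(1L, floor(alpha / 2 * (n_boot + 1L)))
  hi_idx <- min(n_boot, ceiling((1 - alpha / 2) * (n_boot + 1L)))
  ci <- apply(boots, 2L, function(x) sort(x)[c(lo_idx, hi_idx)])
  structure(
    list(
      table = data.frame(
        lag = lags, composite = obs, ci_low = ci[1L, ], ci_high = ci[2L, ],
        significant = !is.na(obs) & (obs < ci[1L, ] | obs > ci[2L, ])
      ),
      n_events = length(events), n_boot = n_boot, alpha = alpha
    ),
    class = "sea_composite"
  )
}

#' @export
print.sea_composite <- function(x, ...) {
  cat("superposed epoch analysis: ", x$n_events, " events, ", x$n_boot,
      " Monte-Carlo draws, alpha = ", x$alpha, "\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Years immediately preceding synchronous periods
#'
#' The deduplicated union, over all periods, of the `k` years before each
#' period's start year, clipped to the study period.
#'
#' @param periods data.frame with a `start` column (e.g. from
#'   [detect_synchronous_periods()]).
#' @param period A [study_period()].
#' @param k Number of pre-event years (default 5).
#' @return Sorted integer vector of years.
#' @export
pre_event_years <- function(periods, period, k = 5L) {
  stopifnot(k >= 1L)
  yrs <- unlist(lapply(periods$start, function(s) seq.int(s - k, s - 1L)))
  sort(unique(yrs[yrs >= period$start_year & yrs <= period$end_year]))
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch–Satterthwaite degrees of freedom
#' and a two-tailed p-value (delegates to [stats::t.test()]).
#'
#' @param sample_a,sample_b Numeric vectors, each of length `>= 2`, with
#'   nonzero variance in at least one.
#' @return List with `t`, `df`, `p`, and the group means `mean_a`, `mean_b`.
#' @export
welch_t <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    stop("each sample needs at least 2 values")
  }
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b)) {
      # identical constant samples: no evidence of a difference
      return(list(t = 0, df = length(sample_a) + length(sample_b) - 2,
                  p = 1, mean_a = mean(sample_a), mean_b = mean(sample_b)))
    }
    stop("both samples are constant; Welch statistic undefined")
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(sample_a), mean_b = mean(sample_b))
}

#' Group comparisons of a climate index against synchronous periods
#'
#' Two Welch-t contrasts of the index values: (a) years inside synchronous
#' periods vs all other years; (b) the `k` years immediately preceding each
#' synchronous period (see [pre_event_years()]) vs all other years. By
#' default pre-event years that also fall inside another synchronous period
#' are kept in the pre-event group; set `exclude_in_period = TRUE` to remove
#' them.
#'
#' @param index A [climate_series()] covering `period`.
#' @param periods Synchronous-period table with `start` and `end` columns.
#' @param period A [study_period()].
#' @param k Pre-event window length in years (default 5).
#' @param exclude_in_period Drop pre-event years inside any synchronous
#'   period from contrast (b)'s first group (default `FALSE`).
#' @return data.frame, one row per contrast, with group sizes, means, SDs,
#'   `t`, `df`, `p`.
#' @export
group_comparisons <- function(index, periods, period, k = 5L,
                              exclude_in_period = FALSE) {
  vals <- series_window(index, period)
  yrs <- period_years(period)
  in_period <- rep(FALSE, period$n)
  for (i in seq_len(nrow(periods))) {
    in_period[yrs >= periods$start[i] & yrs <= periods$end[i]] <- TRUE
  }
  pre <- yrs %in% pre_event_years(periods, period, k)
  if (exclude_in_period) pre <- pre & !in_period
  contrasts <- list(
    synchronous_vs_other = in_period,
    pre_event_vs_other = pre
  )
  rows <- lapply(names(contrasts), function(nm) {
    g1 <- vals[contrasts[[nm]]]
    g2 <- vals[!contrasts[[nm]]]
    if (length(g1) == 0L || length(g2) == 0L) {
      stop("contrast '", nm, "' has an empty group")
    }
    w <- welch_t(g1, g2)
    data.frame(contrast = nm, n1 = length(g1), n2 = length(g2),
               mean1 = mean(g1), mean2 = mean(g2),
               sd1 = stats::sd(g1), sd2 = stats::sd(g2),
               t = w$t, df = w$df, p = w$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
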
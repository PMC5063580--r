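#' Count regions in outbreak per year
#'
#' @param records Named list of [binary_series()], all covering `period`.
#' @param period A [study_period()].
#' @return Integer vector of length `period$n`, named by calendar year: the
#'   number of regions with outbreak status 1 in each year.
#' @export
count_regions <- function(records, period) {
  stopifnot(length(records) >= 1L)
  mat <- vapply(records, series_window, numeric(period$n), period = period)
  counts <- as.integer(rowSums(mat))
  names(counts) <- period_years(period)
  counts
}

#' Detect synchronous outbreak periods
#'
#' A synchronous period is a maximal run of years in which at least
#' `min_regions` regions are simultaneously in outbreak, lasting at least
#' `min_run` years (defaults: 3 of the regions for at least 2 consecutive
#' years). Runs separated by at most `max_bridge` sub-threshold years can be
#' merged, with the bridge years counted inside the merged period; the
#' default is no merging. Participants are all regions with at least one
#' outbreak year anywhere inside the (merged) span. Periods that touch the
#' study-period boundary are flagged as possibly truncated.
#'
#' @param counts Per-year region counts from [count_regions()]; computed from
#'   `records` if `NULL`.
#' @param records Named list of [binary_series()] (used for `counts` when
#'   missing and for participant sets; participant sets are empty if omitted).
#' @param period A [study_period()].
#' @param min_regions Minimum number of simultaneous regions (default 3).
#' @param min_run Minimum period length in years (default 2).
#' @param max_bridge Maximum number of consecutive sub-threshold years to
#'   bridge when merging adjacent runs (default 0).
#' @return A data.frame with columns `start`, `end`, `duration`,
#'   `participants` (semicolon-joined region ids) and `truncated`, ordered by
#'   start year.
#' @export
detect_synchronous_periods <- function(counts = NULL, records = NULL, period,
                                       min_regions = 3L, min_run = 2L,
                                       max_bridge = 0L) {
  stopifnot(min_regions >= 1L, min_run >= 1L, max_bridge >= 0L)
  if (is.null(counts)) {
    if (is.null(records)) stop("provide counts or records")
    counts <- count_regions(records, period)
  }
  stopifnot(length(counts) == period$n)
  above <- counts >= min_regions
  r <- rle(above)
  if (max_bridge > 0L && length(r$lengths) > 2L) {
    # bridge interior FALSE runs of length <= max_bridge
    interior <- seq_along(r$values) > 1L & seq_along(r$values) < length(r$values)
    r$values[interior & !r$values & r$lengths <= max_bridge] <- TRUE
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  starts <- starts[keep]
  ends <- ends[keep]
  yrs0 <- period$start_year - 1L
  out <- data.frame(
    start = yrs0 + starts,
    end = yrs0 + ends,
    duration = ends - starts + 1L
  )
  out$participants <- vapply(seq_len(nrow(out)), function(i) {
    if (is.null(records)) return("")
    p <- study_period(out$start[i], out$end[i])
    ids <- names(records)[vapply(records, function(s) {
      any(series_window(s, p) == 1)
    }, logical(1))]
    paste(ids, collapse = ";")
  }, character(1))
  out$truncated <- out$start == period$start_year | out$end == period$end_year
  out[order(out$start), , drop = FALSE]
}

#' Tabulate synchronous periods
#'
#' @param periods data.frame from [detect_synchronous_periods()] (or any
#'   table with `start`, `end`, `duration`, `participants`).
#' @return The same table, rows sorted by start year, with an `n_regions`
#'   column counting participants.
#' @export
period_table <- function(periods) {
  periods <- periods[order(periods$start), , drop = FALSE]
  periods$n_regions <- vapply(strsplit(periods$participants, ";"), function(p) {
    sum(nzchar(p))
  }, integer(1))
  rownames(periods) <- NULL
  periods
}

#' Fraction of period years with at least k regions in outbreak
#'
#' @param counts Per-year counts from [count_regions()].
#' @param k Threshold number of regions.
#' @return List with `n_years` (count of years with `counts >= k`) and
#'   `fraction` (that count divided by the period length).
#' @export
fraction_years_with_at_least <- function(counts, k) {
  stopifnot(k >= 1L)
  n <- sum(counts >= k)
  list(n_years = n, fraction = n / length(counts))
}

## ---- published reference tables ------------------------------------------

#' Published synchronous-period table for the compiled WSB record
#'
#' The 13 synchronous outbreak periods identified over the 1700--1990 common
#' period of the seven compiled regional western spruce budworm
#' reconstructions, with inclusive start/end years and the regions recording
#' an outbreak in at least one year of each period. The underlying regional
#' binary records are not redistributable, so this table is the in-package
#' worked example for the episode/summary conventions (mean duration
#' 201/13 = 15.46 years, mean quiescent gap 88/12 = 7.33 years). Region codes:
#' BC, WA, MT, ID, OR, CO, NM (the New Mexico record ends in 1990 in the midst
#' of a widespread outbreak, so the final period is truncated).
#'
#' @return data.frame with columns `start`, `end`, `duration`,
#'   `participants`.
#' @examples
#' summarize_episodes(wsb_synchronous_periods())
#' @export
wsb_synchronous_periods <- function() {
  all7 <- "BC;WA;MT;ID;OR;CO;NM"
  data.frame(
    start = c(1702L, 1715L, 1743L, 1785L, 1810L, 1824L, 1844L, 1849L, 1871L,
              1891L, 1938L, 1960L, 1975L),
    end = c(1703L, 1733L, 1776L, 1805L, 1820L, 1838L, 1845L, 1855L, 1878L,
            1934L, 1955L, 1963L, 1990L),
    duration = c(2L, 19L, 34L, 21L, 11L, 15L, 2L, 7L, 8L, 44L, 18L, 4L, 16L),
    participants = c(
      "BC;MT;CO", all7, all7, all7,
      "BC;WA;MT;CO;NM", "WA;MT;OR;CO;NM", "ID;OR;CO", "MT;ID;OR;CO",
      "WA;MT;ID;OR;CO;NM", all7, "BC;WA;MT;ID;OR;NM", "WA;MT;OR;CO", all7
    )
  )
}

#' Published per-region outbreak summaries for the compiled WSB record
#'
#' Reference outbreak-record characteristics for the seven regional
#' reconstructions over the 1700--1990 common period: number of outbreak
#' episodes, mean episode duration (years) and mean quiescent period (years).
#' The per-region records themselves are not redistributable, so these values
#' cannot be recomputed here; they are documented reference values, used in
#' this package to calibrate the synthetic-data generator
#' ([transect_scenario()]).
#'
#' @return data.frame with columns `region_id`, `group` (northwest/southwest),
#'   `n_outbreaks`, `mean_duration`, `mean_quiescent`.
#' @export
wsb_region_summaries <- function() {
  data.frame(
    region_id = c("BC", "WA", "MT", "ID", "OR", "CO", "NM"),
    group = c(rep("northwest", 5L), rep("southwest", 2L)),
    n_outbreaks = c(8L, 14L, 14L, 11L, 15L, 8L, 11L),
    mean_duration = c(12.6, 8.1, 12, 10.3, 7.8, 28.7, 13.8),
    mean_quiescent = c(28.3, 13.1, 8.8, 15.7, 11, 9.7, 13.5)
  )
}
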
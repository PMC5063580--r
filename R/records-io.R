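#' Study period
#'
#' A closed interval of calendar years `[start_year, end_year]` over which all
#' regional records are compared. The analyses in this package are carried out
#' on the common period shared by every record (for the compiled western
#' spruce budworm reconstructions this is 1700--1990, 291 years).
#'
#' @param start_year First calendar year (integer).
#' @param end_year Last calendar year (integer), `>= start_year`.
#'
#' @return An object of class `study_period` with fields `start_year`,
#'   `end_year` and `n = end_year - start_year + 1`.
#' @examples
#' study_period(1700, 1990)$n  # 291
#' @export
study_period <- function(start_year, end_year) {
  start_year <- as.integer(start_year)
  end_year <- as.integer(end_year)
  stopifnot(length(start_year) == 1L, length(end_year) == 1L,
            is.finite(start_year), is.finite(end_year))
  if (start_year > end_year) {
    stop("start_year (", start_year, ") must be <= end_year (", end_year, ")")
  }
  structure(
    list(start_year = start_year, end_year = end_year,
         n = end_year - start_year + 1L),
    class = "study_period"
  )
}

#' @export
print.study_period <- function(x, ...) {
  cat("study period ", x$start_year, "-", x$end_year,
      " (", x$n, " years)\n", sep = "")
  invisible(x)
}

period_years <- function(period) {
  seq.int(period$start_year, period$end_year)
}

new_annual_series <- function(region_id, first_year, values, subclass) {
  stopifnot(length(region_id) == 1L, length(first_year) == 1L)
  values <- as.vector(values, mode = "numeric")
  if (length(values) < 1L) stop("series must contain at least one year")
  if (any(!is.finite(values))) {
    stop("series for region '", region_id, "' contains non-finite values")
  }
  structure(
    list(region_id = as.character(region_id),
         first_year = as.integer(first_year),
         values = values),
    class = c(subclass, "annual_series")
  )
}

#' Annual series constructors
#'
#' Annual series are contiguous per-region records indexed by calendar year.
#' `binary_series()` holds 0/1 outbreak status, `climate_series()` holds
#' real-valued drought-index (e.g. PDSI) values, and `percent_series()` holds
#' fractions in `[0, 1]` of trees recording an outbreak.
#'
#' @param region_id Region label.
#' @param first_year Calendar year of the first value.
#' @param values Numeric vector, one value per consecutive year.
#'
#' @return An `annual_series` object with subclass `binary_series`,
#'   `climate_series` or `percent_series`.
#' @examples
#' binary_series("BC", 1700, c(0, 1, 1, 0))
#' @export
binary_series <- function(region_id, first_year, values) {
  if (any(!(values %in% c(0, 1)))) {
    stop("binary series for region '", region_id,
         "' contains values other than 0/1")
  }
  new_annual_series(region_id, first_year, values, "binary_series")
}

#' @rdname binary_series
#' @export
climate_series <- function(region_id, first_year, values) {
  new_annual_series(region_id, first_year, values, "climate_series")
}

#' @rdname binary_series
#' @export
percent_series <- function(region_id, first_year, values) {
  if (any(values < 0 | values > 1)) {
    stop("percent series for region '", region_id,
         "' contains values outside [0, 1]")
  }
  new_annual_series(region_id, first_year, values, "percent_series")
}

#' @export
print.annual_series <- function(x, ...) {
  cat(class(x)[1L], " '", x$region_id, "': ", x$first_year, "-",
      series_last_year(x), " (", length(x$values), " years)\n", sep = "")
  invisible(x)
}

#' Last calendar year of an annual series
#' @param series An `annual_series`.
#' @return Integer year.
#' @export
series_last_year <- function(series) {
  series$first_year + length(series$values) - 1L
}

series_covers <- function(series, period) {
  series$first_year <= period$start_year &&
    series_last_year(series) >= period$end_year
}

#' Extract the values of a series over a study period
#'
#' @param series An `annual_series`.
#' @param period A [study_period()] fully contained in the series span.
#' @return Numeric vector of length `period$n`, one value per year.
#' @export
series_window <- function(series, period) {
  if (!series_covers(series, period)) {
    stop("series '", series$region_id, "' (", series$first_year, "-",
         series_last_year(series), ") does not cover the study period ",
         period$start_year, "-", period$end_year)
  }
  offset <- period$start_year - series$first_year
  series$values[seq.int(offset + 1L, offset + period$n)]
}

## ---- matrix readers -------------------------------------------------------

# Shared reader for year x region CSV matrices. Leading/trailing NAs are
# trimmed per region; internal NAs are hard errors because every analysis
# assumes contiguous annual records.
read_annual_matrix <- function(path, make_series, kind) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix in '", path, "' needs a year column plus ",
                          "at least one region column")
  if (tolower(names(df)[1L]) != "year") {
    stop("first column of '", path, "' must be 'year', found '",
         names(df)[1L], "'")
  }
  years <- df[[1L]]
  if (any(is.na(years)) || any(diff(years) != 1L)) {
    stop("year column of '", path, "' must be consecutive ascending years")
  }
  out <- list()
  for (j in seq(2L, ncol(df))) {
    region <- names(df)[j]
    raw <- df[[j]]
    empty <- is.na(raw) | trimws(as.character(raw)) == ""
    col <- suppressWarnings(as.numeric(as.character(raw)))
    bad <- !empty & is.na(col)
    if (any(bad)) {
      stop("non-numeric value '", raw[bad][1L], "' for region '", region,
           "' at year ", years[which(bad)[1L]], " in '", path, "'")
    }
    present <- !is.na(col)
    if (!any(present)) stop("region '", region, "' in '", path,
                            "' has no data")
    first <- which(present)[1L]
    last <- which(present)[sum(present)]
    if (any(!present[first:last])) {
      gap <- first - 1L + which(!present[first:last])[1L]
      stop("region '", region, "' in '", path, "' has an internal gap at year ",
           years[gap], "; records must be contiguous")
    }
    vals <- col[first:last]
    if (kind == "binary" && any(!(vals %in% c(0, 1)))) {
      bad <- first - 1L + which(!(vals %in% c(0, 1)))[1L]
      stop("non-binary value '", vals[bad - first + 1L], "' for region '",
           region, "' at year ", years[bad], " in '", path, "'")
    }
    if (kind == "percent" && any(vals < 0 | vals > 1)) {
      bad <- first - 1L + which(vals < 0 | vals > 1)[1L]
      stop("value outside [0, 1] for region '", region, "' at year ",
           years[bad], " in '", path, "'")
    }
    out[[region]] <- make_series(region, years[first], vals)
  }
  out
}

#' Read annual year-by-region matrices
#'
#' The on-disk layout is a CSV with a `year` column (consecutive ascending
#' calendar years) and one column per region. Empty cells are allowed only at
#' the leading/trailing margins of a region's column and are trimmed; an
#' internal gap is an error. `read_binary_matrix()` additionally requires all
#' cells to be 0 or 1, and `read_percent_matrix()` requires fractions in
#' `[0, 1]`.
#'
#' @param path Path to a CSV file.
#' @return A named list of [binary_series()], [climate_series()] or
#'   [percent_series()] objects, one per region column.
#' @seealso [write_annual_matrix()] for the inverse operation.
#' @export
read_binary_matrix <- function(path) {
  read_annual_matrix(path, binary_series, "binary")
}

#' @rdname read_binary_matrix
#' @export
read_climate_matrix <- function(path) {
  read_annual_matrix(path, climate_series, "climate")
}

#' @rdname read_binary_matrix
#' @export
read_percent_matrix <- function(path) {
  read_annual_matrix(path, percent_series, "percent")
}

#' Write a collection of annual series as a year-by-region CSV
#'
#' Regions with different spans are aligned on the union of years; years a
#' region does not cover are written as empty cells (legal only at the
#' margins, which is the only way they can arise from `annual_series`
#' objects).
#'
#' @param series_list Named list of `annual_series` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annual_matrix <- function(series_list, path) {
  stopifnot(length(series_list) >= 1L)
  firsts <- vapply(series_list, function(s) s$first_year, integer(1))
  lasts <- vapply(series_list, series_last_year, integer(1))
  years <- seq.int(min(firsts), max(lasts))
  df <- data.frame(year = years)
  for (s in series_list) {
    col <- rep(NA_real_, length(years))
    col[match(seq.int(s$first_year, series_last_year(s)), years)] <- s$values
    df[[s$region_id]] <- col
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read region centroid geometry
#'
#' @param path CSV with columns `region_id,east_km,north_km` giving centroid
#'   coordinates on a common projected plane, in km.
#' @return A data.frame with those three columns (a "region set").
#' @export
read_region_set <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region_id", "east_km", "north_km")
  if (!all(need %in% names(df))) {
    stop("region geometry file '", path, "' must have columns ",
         paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$region_id)) stop("duplicate region_id in '", path, "'")
  if (any(!is.finite(df$east_km)) || any(!is.finite(df$north_km))) {
    stop("non-finite coordinates in '", path, "'")
  }
  df[need]
}

## ---- common period and episodes ------------------------------------------

#' Common period shared by a collection of annual series
#'
#' @param series_list List of `annual_series` objects.
#' @return A [study_period()] spanning the intersection of all series spans.
#'   Errors if the intersection is empty.
#' @examples
#' common_period(list(binary_series("a", 1700, rep(0, 291)),
#'                    binary_series("b", 1650, rep(0, 346))))
#' @export
common_period <- function(series_list) {
  stopifnot(length(series_list) >= 1L)
  start <- max(vapply(series_list, function(s) s$first_year, integer(1)))
  end <- min(vapply(series_list, series_last_year, integer(1)))
  if (start > end) {
    stop("series have no common period (intersection of spans is empty)")
  }
  study_period(start, end)
}

#' Extract outbreak episodes from a binary series
#'
#' An episode is a maximal run of consecutive outbreak (1) years. Durations
#' are inclusive: an episode covering 1702--1703 has duration 2.
#'
#' @param series A [binary_series()].
#' @param period Optional [study_period()]; defaults to the series' own span.
#' @return A data.frame with integer columns `start`, `end`, `duration`
#'   (one row per episode, ordered by start year; zero rows if the series has
#'   no outbreak years).
#' @examples
#' s <- binary_series("x", 1700, c(0, 1, 1, 0, 1, 0))
#' extract_episodes(s)  # episodes 1701-1702 and 1704-1704
#' @export
extract_episodes <- function(series, period = NULL) {
  if (is.null(period)) {
    period <- study_period(series$first_year, series_last_year(series))
  }
  x <- series_window(series, period)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1
  data.frame(
    start = period$start_year + starts[keep] - 1L,
    end = period$start_year + ends[keep] - 1L,
    duration = r$lengths[keep]
  )
}

#' Rebuild a binary series from an episode table
#'
#' Inverse of [extract_episodes()]: years inside any `[start, end]` interval
#' become 1, all other period years 0.
#'
#' @param episodes data.frame with `start` and `end` columns.
#' @param period [study_period()] the output series should span.
#' @param region_id Label for the rebuilt series.
#' @return A [binary_series()].
#' @export
episodes_to_series <- function(episodes, period, region_id = "episodes") {
  vals <- rep(0, period$n)
  yrs <- period_years(period)
  for (i in seq_len(nrow(episodes))) {
    vals[yrs >= episodes$start[i] & yrs <= episodes$end[i]] <- 1
  }
  binary_series(region_id, period$start_year, vals)
}

#' Summarize an episode table
#'
#' Mean inclusive duration and mean quiescent period. Quiescent gaps are
#' counted only strictly between consecutive episodes
#' (`gap = next start - previous end - 1`), never before the first or after
#' the last episode; with fewer than two episodes the mean gap is undefined
#' (`NA`).
#'
#' @param episodes data.frame as returned by [extract_episodes()] (or any
#'   table with `start`, `end`, `duration` columns, e.g. a synchronous-period
#'   table).
#' @return List with `n_episodes`, `mean_duration`, `mean_quiescent`.
#' @examples
#' summarize_episodes(data.frame(start = c(1700, 1705), end = c(1701, 1706),
#'                               duration = c(2, 2)))  # mean gap 3
#' @export
summarize_episodes <- function(episodes) {
  n <- nrow(episodes)
  if (n == 0L) {
    return(list(n_episodes = 0L, mean_duration = NA_real_,
                mean_quiescent = NA_real_))
  }
  episodes <- episodes[order(episodes$start), , drop = FALSE]
  gaps <- if (n >= 2L) {
    episodes$start[-1L] - episodes$end[-n] - 1L
  } else {
    numeric(0)
  }
  list(
    n_episodes = n,
    mean_duration = mean(episodes$duration),
    mean_quiescent = if (n >= 2L) mean(gaps) else NA_real_
  )
}
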
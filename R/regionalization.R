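#' Pool per-site tree counts into a regional percent series
#'
#' Regional outbreak fractions are tree-weighted: the pooled fraction for a
#' year is the total number of trees recording an outbreak across all sites
#' divided by the total number of trees sampled, not the mean of per-site
#' fractions.
#'
#' @param outbreak_counts Year-by-site matrix (or data.frame) of trees
#'   recording an outbreak.
#' @param total_counts Year-by-site matrix of trees sampled, same shape.
#' @param first_year Calendar year of the first row.
#' @param region_id Label for the pooled series.
#' @return A [percent_series()].
#' @examples
#' pool_sites(cbind(4, 6), cbind(10, 10), 1900)$values  # 0.5
#' @export
pool_sites <- function(outbreak_counts, total_counts, first_year,
                       region_id = "region") {
  outbreak_counts <- as.matrix(outbreak_counts)
  total_counts <- as.matrix(total_counts)
  if (!identical(dim(outbreak_counts), dim(total_counts))) {
    stop("outbreak_counts and total_counts must have the same dimensions")
  }
  if (any(outbreak_counts < 0) || any(total_counts < outbreak_counts)) {
    stop("counts must satisfy 0 <= outbreak trees <= sampled trees")
  }
  tot <- rowSums(total_counts)
  if (any(tot <= 0)) {
    stop("year ", first_year + which(tot <= 0)[1L] - 1L,
         " has zero sampled trees across all sites")
  }
  percent_series(region_id, first_year, rowSums(outbreak_counts) / tot)
}

#' Convert a percent-of-trees series into a regional binary outbreak record
#'
#' A year is labelled as a regional outbreak year iff it belongs to a maximal
#' run of at least `min_run` consecutive years in which the fraction of trees
#' recording an outbreak is at least `threshold`. With the defaults this is
#' the "at least 40% of trees for at least two years" rule used to regionalize
#' stand-level western spruce budworm reconstructions. The threshold is a weak
#' inequality applied to the exact input values (no rounding).
#'
#' @param percent A [percent_series()].
#' @param threshold Fraction in `(0, 1]`; default 0.40.
#' @param min_run Minimum run length in years; default 2.
#' @return A [binary_series()] over the same span.
#' @examples
#' p <- percent_series("r", 1900, c(0.39, 0.40, 0.41, 0.10, 0.40))
#' regionalize(p)$values  # 0 1 1 0 0
#' @export
regionalize <- function(percent, threshold = 0.40, min_run = 2L) {
  stopifnot(inherits(percent, "percent_series"),
            threshold > 0, threshold <= 1, min_run >= 1)
  above <- as.numeric(percent$values >= threshold)
  r <- rle(above)
  r$values[r$values == 1 & r$lengths < min_run] <- 0
  binary_series(percent$region_id, percent$first_year, inverse.rle(r))
}
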
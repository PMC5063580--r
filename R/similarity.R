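#' Agreement counts for a pair of binary records
#'
#' Tallies, over the study period, the years in which both regions are in
#' outbreak (`a`), both out (`b`), only the first in (`c`) and only the
#' second in (`d`); `a + b + c + d` equals the period length.
#'
#' @param x,y [binary_series()] objects covering `period`.
#' @param period A [study_period()].
#' @return List with integer fields `a`, `b`, `c`, `d`.
#' @export
pair_agreement <- function(x, y, period) {
  vx <- series_window(x, period)
  vy <- series_window(y, period)
  list(
    a = sum(vx == 1 & vy == 1),
    b = sum(vx == 0 & vy == 0),
    c = sum(vx == 1 & vy == 0),
    d = sum(vx == 0 & vy == 1)
  )
}

#' Outbreak-history similarity between two regions
#'
#' The fraction of common-period years in which the two regions record the
#' same outbreak status: `(a + b) / (a + b + c + d)` in terms of the
#' [pair_agreement()] counts. Note this is the simple matching coefficient —
#' joint absences (`b`) count as agreement — although the source literature
#' labels it a Jaccard index; the formula with `b` in the numerator is what
#' is implemented.
#'
#' @inheritParams pair_agreement
#' @return Similarity in `[0, 1]`.
#' @export
outbreak_similarity <- function(x, y, period) {
  ct <- pair_agreement(x, y, period)
  (ct$a + ct$b) / period$n
}

#' Climate similarity between two regions
#'
#' The negative of the mean annual distance in climate space:
#' `-(1/n) * sum_t sqrt((x_t - y_t)^2)`, i.e. minus the mean absolute annual
#' difference of the two drought-index series. Always `<= 0`, equal to 0 iff
#' the series are identical over the period.
#'
#' @param x,y [climate_series()] objects covering `period`.
#' @param period A [study_period()].
#' @return Similarity `<= 0`.
#' @export
climate_similarity <- function(x, y, period) {
  -mean(abs(series_window(x, period) - series_window(y, period)))
}

pairwise_matrix <- function(ids, fun) {
  nr <- length(ids)
  m <- matrix(NA_real_, nr, nr, dimnames = list(ids, ids))
  for (i in seq_len(nr - 1L)) {
    for (j in seq(i + 1L, nr)) {
      m[i, j] <- m[j, i] <- fun(i, j)
    }
  }
  m
}

#' Pairwise similarity matrices
#'
#' Apply [outbreak_similarity()] or [climate_similarity()] to every region
#' pair. The diagonal is left `NA` (self-similarity is not used anywhere).
#'
#' @param records Named list of [binary_series()] or [climate_series()].
#' @param period A [study_period()].
#' @return Symmetric region-by-region matrix with `NA` diagonal.
#' @export
outbreak_similarity_matrix <- function(records, period) {
  pairwise_matrix(names(records), function(i, j) {
    outbreak_similarity(records[[i]], records[[j]], period)
  })
}

#' @rdname outbreak_similarity_matrix
#' @export
climate_similarity_matrix <- function(records, period) {
  pairwise_matrix(names(records), function(i, j) {
    climate_similarity(records[[i]], records[[j]], period)
  })
}

#' Euclidean centroid distances between regions
#'
#' @param regions data.frame with `region_id`, `east_km`, `north_km`
#'   (projected centroid coordinates in km, see [read_region_set()]).
#' @return Symmetric distance matrix in km with `NA` diagonal. Duplicate
#'   coordinates are allowed (distance 0) but trigger a warning.
#' @export
centroid_distances <- function(regions) {
  stopifnot(nrow(regions) >= 2L)
  m <- as.matrix(stats::dist(regions[, c("east_km", "north_km")]))
  dimnames(m) <- list(regions$region_id, regions$region_id)
  if (any(m[upper.tri(m)] == 0)) {
    warning("some regions share identical centroid coordinates (distance 0)")
  }
  diag(m) <- NA_real_
  m
}

upper_tri_values <- function(m) m[upper.tri(m)]

check_same_regions <- function(...) {
  mats <- list(...)
  ids <- rownames(mats[[1L]])
  for (m in mats[-1L]) {
    if (!identical(rownames(m), ids)) {
      stop("pairwise matrices must share the same region set and order")
    }
  }
  invisible(ids)
}

#' Distance decay of similarity
#'
#' Ordinary least squares of pairwise similarity on pairwise distance, using
#' each unordered region pair once (upper triangle).
#'
#' @param similarity,distance Symmetric pairwise matrices over the same
#'   region set.
#' @return List with `slope`, `intercept`, `r_squared`, `n_pairs` and the
#'   fitted `lm` object (`model`).
#' @export
distance_decay_regression <- function(similarity, distance) {
  check_same_regions(similarity, distance)
  df <- data.frame(similarity = upper_tri_values(similarity),
                   distance = upper_tri_values(distance))
  if (nrow(df) < 3L) stop("need at least 3 region pairs for a regression")
  fit <- stats::lm(similarity ~ distance, data = df)
  # suppress summary.lm's "essentially perfect fit" note on exact inputs
  r2 <- if (stats::var(df$similarity) == 0) 0 else
    suppressWarnings(summary(fit)$r.squared)
  list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = r2,
    n_pairs = nrow(df),
    model = fit
  )
}

## ---- Mantel tests ---------------------------------------------------------

mantel_perm_p <- function(r_obs, r_perm, alternative) {
  # identity permutation is included in numerator and denominator
  hits <- switch(alternative,
    two.sided = sum(abs(r_perm) >= abs(r_obs)),
    greater = sum(r_perm >= r_obs),
    less = sum(r_perm <= r_obs)
  )
  (1 + hits) / (1 + length(r_perm))
}

#' Mantel permutation test
#'
#' Pearson correlation between the upper triangles of two pairwise matrices,
#' with significance from simultaneous row/column relabelings of the second
#' matrix. The default test is two-tailed on `|r|`; the identity permutation
#' is included in the p-value count, so `p` lies in
#' `[1/(n_perm + 1), 1]`.
#'
#' @param a,b Symmetric pairwise matrices over the same region set.
#' @param n_perm Number of random permutations (default 10000).
#' @param seed Optional integer seed.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List with `r`, `p`, `n_perm`, `alternative`.
#' @export
mantel_test <- function(a, b, n_perm = 10000L, seed = NULL,
                        alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  check_same_regions(a, b)
  va <- upper_tri_values(a)
  if (stats::sd(va) == 0 || stats::sd(upper_tri_values(b)) == 0) {
    stop("zero variance in a matrix's upper triangle; Mantel r is undefined")
  }
  if (!is.null(seed)) set.seed(seed)
  r_obs <- stats::cor(va, upper_tri_values(b))
  nr <- nrow(a)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(nr)
    stats::cor(va, upper_tri_values(b[idx, idx]))
  }, numeric(1))
  list(r = r_obs, p = mantel_perm_p(r_obs, r_perm, alternative),
       n_perm = n_perm, alternative = alternative)
}

# residuals of the upper triangle of m on the upper triangle of c,
# reassembled as a symmetric matrix so it can be relabelled
residual_matrix <- function(m, cond) {
  vm <- upper_tri_values(m)
  vc <- upper_tri_values(cond)
  res <- stats::residuals(stats::lm(vm ~ vc))
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  out[upper.tri(out)] <- res
  out <- out + t(out)
  diag(out) <- NA_real_
  out
}

#' Partial Mantel permutation test
#'
#' Correlation between two pairwise matrices after removing, from each, the
#' variability explained by a third (typically geographic distance): both
#' `a` and `b` are residualized on `c` by OLS over the upper triangle, the
#' statistic is the Pearson correlation of the residuals, and the null
#' distribution comes from simultaneous row/column relabelings of the
#' residualized `a` matrix. If `b` is (numerically) fully explained by `c`
#' the residual variance vanishes and `r` is reported as 0 with a warning.
#'
#' @param a,b Pairwise matrices to correlate.
#' @param c Conditioning pairwise matrix.
#' @inheritParams mantel_test
#' @return List with `r`, `p`, `n_perm`, `alternative`.
#' @export
partial_mantel_test <- function(a, b, c, n_perm = 10000L, seed = NULL,
                                alternative = c("two.sided", "greater",
                                                "less")) {
  alternative <- match.arg(alternative)
  check_same_regions(a, b, c)
  res_a <- residual_matrix(a, c)
  res_b_v <- stats::residuals(
    stats::lm(upper_tri_values(b) ~ upper_tri_values(c))
  )
  tol <- 1e-12 * max(stats::var(upper_tri_values(b)), 1e-300)
  if (stats::var(res_b_v) <= tol || stats::var(upper_tri_values(res_a)) <= tol) {
    warning("one matrix is fully explained by the conditioning matrix; ",
            "partial Mantel r set to 0")
    return(list(r = 0, p = 1, n_perm = n_perm, alternative = alternative))
  }
  if (!is.null(seed)) set.seed(seed)
  r_obs <- stats::cor(upper_tri_values(res_a), res_b_v)
  nr <- nrow(a)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(nr)
    stats::cor(upper_tri_values(res_a[idx, idx]), res_b_v)
  }, numeric(1))
  list(r = r_obs, p = mantel_perm_p(r_obs, r_perm, alternative),
       n_perm = n_perm, alternative = alternative)
}
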
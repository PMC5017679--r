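#' Log accuracy ratio
#'
#' \eqn{\alpha = \log\frac{\hat N + 1}{N + 1}} (natural log; the +1 shift
#' keeps zero estimates finite).  \eqn{\alpha = 0} for a perfect estimate;
#' positive values are overestimates.
#'
#' @param N_hat estimated population size(s), >= 0
#' @param N_true true population size(s), >= 0
#' @export
alpha_log_ratio <- function(N_hat, N_true) {
  if (any(N_hat < 0) || any(N_true < 0)) stop("population sizes must be >= 0")
  log((N_hat + 1) / (N_true + 1))
}

#' Regression of estimated on true population sizes
#'
#' Ordinary least squares of \eqn{\log(\hat N + 1)} on \eqn{\log(N + 1)}
#' (the same +1 shift as [alpha_log_ratio()]).  Perfect estimates give
#' slope \eqn{\beta = 1} and \eqn{R^2 = 1}.
#'
#' @param N_hat,N_true aligned vectors (>= 3 pairs, with variance in truth)
#' @return list with `beta`, `r_squared`, `intercept`, `n`
#' @export
regression_metrics <- function(N_hat, N_true) {
  ok <- is.finite(N_hat) & is.finite(N_true)
  x <- log(N_true[ok] + 1)
  y <- log(N_hat[ok] + 1)
  if (length(x) < 3L) stop("need >= 3 pairs")
  if (stats::var(x) == 0) stop("no variance in the true sizes")
  beta <- stats::cov(x, y) / stats::var(x)
  list(beta = beta,
       r_squared = if (stats::var(y) == 0) 1 else stats::cor(x, y)^2,
       intercept = mean(y) - beta * mean(x), n = length(x))
}

#' Interval coverage
#'
#' Fraction of true values falling inside their interval (inclusive).
#'
#' @param N_true true values
#' @param lo,hi interval bounds, aligned with `N_true`
#' @export
interval_coverage <- function(N_true, lo, hi) {
  if (length(lo) != length(N_true) || length(hi) != length(N_true)) {
    stop("intervals must align with the true values")
  }
  if (any(lo > hi, na.rm = TRUE)) stop("malformed interval (lo > hi)")
  ok <- !is.na(lo) & !is.na(hi)
  mean(lo[ok] <= N_true[ok] & N_true[ok] <= hi[ok])
}

#' Spatial rank correlation on a regular grid
#'
#' Decomposes the domain into a regular grid (the full design uses 12 x 6
#' cells of 100 x 100 km), sums the true number of individuals per cell
#' from a mid-season location snapshot, and computes Spearman's rank
#' correlation with the predicted per-cell totals (ties mid-ranked).
#'
#' @param x,y true individual locations (mid-season snapshot)
#' @param w weight per location (group size)
#' @param predicted predicted totals per cell, in cell order (x fastest)
#' @param origin grid origin (lower-left, km)
#' @param cell_km cell size (km)
#' @param nx,ny grid dimensions
#' @return Spearman correlation, or `NA` (flagged by attribute
#'   `degenerate`) when either vector is constant
#' @export
grid_rank_correlation <- function(x, y, w = 1, predicted, origin = c(0, 0),
                                  cell_km = 100, nx, ny) {
  if (length(predicted) != nx * ny) stop("`predicted` must have nx*ny cells")
  ix <- floor((x - origin[1]) / cell_km) + 1
  iy <- floor((y - origin[2]) / cell_km) + 1
  ix <- pmin(pmax(ix, 1), nx)
  iy <- pmin(pmax(iy, 1), ny)
  cell <- (iy - 1) * nx + ix
  truth <- vapply(seq_len(nx * ny),
                  function(c) sum(rep_len(w, length(x))[cell == c]),
                  numeric(1))
  if (stats::sd(truth) == 0 || stats::sd(predicted) == 0) {
    out <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  stats::cor(truth, predicted, method = "spearman")
}

#' Classify an estimate as failed
#'
#' An estimate fails when the fit reported convergence problems, produced
#' non-finite densities, or the estimated total population size is below
#' `lower` (1) or above `upper` (1000) individuals.  Failed replicates are
#' excluded from metric aggregation and counted in the failed fraction.
#'
#' @param N_hat estimated total (point estimate or posterior median)
#' @param converged did the inference converge? (default TRUE)
#' @param lower,upper plausibility bounds on the total
#' @return logical
#' @export
classify_failure <- function(N_hat, converged = TRUE, lower = 1,
                             upper = 1000) {
  !isTRUE(converged) || !all(is.finite(N_hat)) ||
    any(N_hat < lower) || any(N_hat > upper)
}
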
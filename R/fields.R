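#' Matern covariance function
#'
#' \eqn{C(d) = \sigma^2 \, 2^{1-\nu}/\Gamma(\nu)\, (\kappa d)^\nu K_\nu(\kappa d)},
#' with \eqn{C(0) = \sigma^2}.  \eqn{\kappa} is the inverse spatial scale
#' (1/km) and \eqn{\nu} the smoothness; \eqn{\nu = 1} is used throughout
#' (the 2-D SPDE alpha = 2 convention), \eqn{\nu = 1/2} gives the
#' exponential covariance \eqn{\sigma^2 e^{-\kappa d}}.
#'
#' @param d distances (km), >= 0; vector or matrix
#' @param variance marginal variance \eqn{\sigma^2} > 0
#' @param kappa inverse range (1/km) > 0
#' @param nu smoothness > 0
#' @return covariance values with the shape of `d`
#' @export
matern_covariance <- function(d, variance, kappa, nu = 1) {
  if (variance <= 0 || kappa <= 0 || nu <= 0) {
    stop("`variance`, `kappa` and `nu` must all be > 0")
  }
  if (any(d < 0)) stop("distances must be >= 0")
  x <- kappa * d
  out <- d
  pos <- x > 0
  # exponentially scaled Bessel avoids underflow at large kappa*d
  out[pos] <- variance * 2^(1 - nu) / gamma(nu) * x[pos]^nu *
    besselK(x[pos], nu, expon.scaled = TRUE) * exp(-x[pos])
  out[!pos] <- variance
  out
}

#' Simulate a Matern Gaussian random field at points
#'
#' Draws one realization of a zero-mean Gaussian field with Matern
#' covariance at the supplied points (exact, via Cholesky of the covariance
#' matrix; suitable for up to a few thousand points).
#'
#' @param x,y point coordinates (km)
#' @param scale spatial scale (km); the inverse range is `1/scale`
#' @param variance marginal variance
#' @param nu smoothness (default 1)
#' @param jitter diagonal jitter stabilizing the Cholesky
#' @return numeric vector of field values
#' @export
matern_field <- function(x, y, scale, variance, nu = 1, jitter = 1e-8) {
  pts <- cbind(x, y)
  d <- as.matrix(stats::dist(pts))
  cv <- matern_covariance(d, variance, 1 / scale, nu)
  L <- chol(cv + diag(jitter * variance, nrow(pts)))
  drop(crossprod(L, stats::rnorm(nrow(pts))))
}

# Matern field sampled on a coarse grid over the domain bounding box and
# bilinearly interpolated to arbitrary points.  Used for the heterogeneous
# initial-distribution scenarios, where field values are needed at many
# locations but the field itself is smooth at `scale`.
matern_field_grid <- function(domain, scale, variance, nu = 1,
                              spacing = scale / 4) {
  bb <- domain$bbox
  gx <- seq(bb["xmin"] - spacing, bb["xmax"] + spacing, by = spacing)
  gy <- seq(bb["ymin"] - spacing, bb["ymax"] + spacing, by = spacing)
  g <- expand.grid(x = gx, y = gy)
  f <- matern_field(g$x, g$y, scale, variance, nu)
  fmat <- matrix(f, length(gx), length(gy))
  list(gx = gx, gy = gy, f = fmat,
       interp = function(px, py) bilinear_interp(gx, gy, fmat, px, py))
}

bilinear_interp <- function(gx, gy, fmat, px, py) {
  ix <- findInterval(px, gx, all.inside = TRUE)
  iy <- findInterval(py, gy, all.inside = TRUE)
  x1 <- gx[ix]; x2 <- gx[ix + 1]; y1 <- gy[iy]; y2 <- gy[iy + 1]
  tx <- (px - x1) / (x2 - x1); ty <- (py - y1) / (y2 - y1)
  f11 <- fmat[cbind(ix, iy)];     f21 <- fmat[cbind(ix + 1, iy)]
  f12 <- fmat[cbind(ix, iy + 1)]; f22 <- fmat[cbind(ix + 1, iy + 1)]
  (1 - tx) * (1 - ty) * f11 + tx * (1 - ty) * f21 +
    (1 - tx) * ty * f12 + tx * ty * f22
}
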
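#' Integrate density draws to population totals
#'
#' Riemann sum of \eqn{\rho(s,t) = a(s,t) h(s)} over the cells of an
#' integration grid: per posterior draw,
#' \eqn{N = \sum_{\mathrm{cells}} a \, h \, A_{\mathrm{cell}}}.
#'
#' @param density_draws matrix (draws x cells) of density draws `a`, or a
#'   vector (one draw)
#' @param h habitat weight per cell (recycled if scalar)
#' @param cell_area cell area (km^2) per cell (recycled if scalar)
#' @param fraction in-region area fraction per cell (recycled; boundary
#'   cells < 1)
#' @return numeric vector of population-total draws
#' @export
integrate_population <- function(density_draws, h = 1, cell_area,
                                 fraction = 1) {
  m <- if (is.matrix(density_draws)) density_draws else
    matrix(density_draws, nrow = 1)
  nc <- ncol(m)
  wt <- rep_len(h, nc) * rep_len(cell_area, nc) * rep_len(fraction, nc)
  drop(m %*% wt)
}

#' Equal-tailed credible interval
#'
#' @param draws posterior draws (>= 100)
#' @param level interval level in (0, 1)
#' @return named vector `lo`, `hi`
#' @export
credible_interval <- function(draws, level = 0.95) {
  if (length(draws) < 100L) stop("need >= 100 draws")
  q <- stats::quantile(draws, c((1 - level) / 2, (1 + level) / 2),
                       names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Build an integration grid over a region
#'
#' Square cells of side `cell_km` covering `region` (a `study_domain`;
#' defaults to the full domain), with the in-domain area fraction of each
#' cell estimated by sub-sampling (boundary cells get fractional weight).
#' Cells entirely outside are dropped.
#'
#' @param domain the study domain clipping every cell
#' @param region optional sub-region (`study_domain`) to integrate over
#' @param raster a `habitat_raster` supplying the class of each cell centre
#' @param cell_km grid resolution (km)
#' @param subsample sub-sampling factor per axis for boundary fractions
#' @return data frame: `x`, `y` (centres), `class`, `fraction`, `area`
#' @export
integration_grid <- function(domain, raster, region = NULL, cell_km = 5,
                             subsample = 10L) {
  reg <- region %||% domain
  bb <- reg$bbox
  cx <- seq(bb["xmin"] + cell_km / 2, bb["xmax"], by = cell_km)
  cy <- seq(bb["ymin"] + cell_km / 2, bb["ymax"], by = cell_km)
  g <- expand.grid(x = cx, y = cy)
  inside <- function(px, py) {
    ok <- domain_contains(domain, px, py)
    if (!is.null(region)) ok <- ok & domain_contains(region, px, py)
    ok
  }
  # coarse pass on centres, refine all cells by subsampling
  off <- (seq_len(subsample) - 0.5) / subsample - 0.5
  frac <- numeric(nrow(g))
  for (ox in off) for (oy in off) {
    frac <- frac + inside(g$x + ox * cell_km, g$y + oy * cell_km)
  }
  frac <- frac / subsample^2
  keep <- frac > 0
  g <- g[keep, , drop = FALSE]
  # cell centres of kept boundary cells can lie outside the raster extent:
  # clamp lookups to the raster
  rx <- pmin(pmax(g$x, raster$origin[["x"]] + 1e-9),
             raster$origin[["x"]] + raster$nx * raster$cell_size - 1e-9)
  ry <- pmin(pmax(g$y, raster$origin[["y"]] + 1e-9),
             raster$origin[["y"]] + raster$ny * raster$cell_size - 1e-9)
  data.frame(x = g$x, y = g$y, class = habitat_at(raster, rx, ry),
             fraction = frac[keep], area = cell_km^2)
}

#' Posterior population size in a region
#'
#' Combines [predict_density_field()] (or the temporal model's constant
#' density) with habitat weights over an integration grid, returning draws
#' and equal-tailed credible intervals of \eqn{N(\Lambda, t)}.
#'
#' @param fit a converged `rem_fit`
#' @param domain,raster,region,cell_km see [integration_grid()]
#' @param weights named habitat weights `h`
#' @param year year to integrate
#' @param levels credible-interval levels
#' @param n_draws_max cap on posterior draws used
#' @return object of class `population_estimate`: `draws`, `median`,
#'   `intervals` (rows lo/hi), `year`
#' @export
population_estimate <- function(fit, domain, raster, weights, year,
                                region = NULL, cell_km = 5,
                                levels = c(0.5, 0.95), n_draws_max = 200) {
  grid <- integration_grid(domain, raster, region, cell_km)
  h <- weights_by_code(raster, weights)[grid$class]
  a <- predict_density_field(fit, cbind(grid$x, grid$y), year, n_draws_max)
  draws <- integrate_population(a, h, grid$area, grid$fraction)
  iv <- sapply(levels, function(lv) {
    stats::quantile(draws, c((1 - lv) / 2, (1 + lv) / 2), names = FALSE)
  })
  dimnames(iv) <- list(c("lo", "hi"), paste0(levels * 100, "%"))
  structure(list(draws = draws, median = stats::median(draws),
                 intervals = iv, year = year),
            class = "population_estimate")
}

#' @export
print.population_estimate <- function(x, ...) {
  cat(sprintf("Population estimate, year %s: median %.1f\n",
              format(x$year), x$median))
  for (j in seq_len(ncol(x$intervals))) {
    cat(sprintf("  %s CrI: [%.1f, %.1f]\n", colnames(x$intervals)[j],
                x$intervals["lo", j], x$intervals["hi", j]))
  }
  invisible(x)
}
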
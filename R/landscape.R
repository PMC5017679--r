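#' Study domain
#'
#' Defines the planar study area \eqn{\Omega} within which animals move and
#' surveys are placed.  Coordinates are planar kilometres (an equal-area
#' projection is assumed for user-supplied data).  The default is a
#' Finland-like rectangle of 400 x 830.44 km, i.e. 332,176 km^2.
#'
#' @param boundary optional two-column matrix (x, y) of polygon vertices in
#'   km, listed once (the closing edge is implicit).  The polygon must be
#'   simple and enclose a positive area.
#' @param width,height dimensions (km) of the default rectangular domain,
#'   used only when `boundary` is `NULL`.
#' @return An object of class `study_domain` with elements `boundary`
#'   (vertex matrix), `area` (km^2) and `bbox` (xmin, xmax, ymin, ymax).
#' @export
study_domain <- function(boundary = NULL, width = 400, height = 830.44) {
  if (is.null(boundary)) {
    boundary <- cbind(x = c(0, width, width, 0), y = c(0, 0, height, height))
  }
  boundary <- as.matrix(boundary)
  if (ncol(boundary) != 2L || nrow(boundary) < 3L) {
    stop("`boundary` must be a matrix with >= 3 rows and 2 columns (x, y)")
  }
  storage.mode(boundary) <- "double"
  if (anyNA(boundary)) stop("`boundary` contains missing coordinates")
  # drop an explicitly repeated closing vertex
  n <- nrow(boundary)
  if (all(boundary[1L, ] == boundary[n, ])) boundary <- boundary[-n, , drop = FALSE]
  area <- polygon_area(boundary)
  if (area < 0) {  # enforce counter-clockwise orientation
    boundary <- boundary[rev(seq_len(nrow(boundary))), , drop = FALSE]
    area <- -area
  }
  if (area <= 0) stop("domain polygon has zero area")
  structure(list(
    boundary = unname(boundary),
    area = area,
    bbox = c(xmin = min(boundary[, 1]), xmax = max(boundary[, 1]),
             ymin = min(boundary[, 2]), ymax = max(boundary[, 2]))
  ), class = "study_domain")
}

#' @export
print.study_domain <- function(x, ...) {
  cat(sprintf("Study domain: %d-vertex polygon, area %.0f km^2\n",
              nrow(x$boundary), x$area))
  invisible(x)
}

#' Domain area
#' @param domain a `study_domain`
#' @return area in km^2
#' @export
domain_area <- function(domain) domain$area

# Shoelace signed area (positive = counter-clockwise).
polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Point-in-domain test
#'
#' Even-odd (ray casting) point-in-polygon test, vectorized over points.
#' Points lying on the boundary count as inside.
#'
#' @param domain a `study_domain`
#' @param x,y point coordinates (km), equal-length vectors
#' @return logical vector
#' @export
domain_contains <- function(domain, x, y) {
  v <- domain$boundary
  nv <- nrow(v)
  n <- length(x)
  inside <- rep(FALSE, n)
  onb <- rep(FALSE, n)
  j <- nv
  for (i in seq_len(nv)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
    # boundary check: point within the segment's bounding box and collinear
    seg <- abs((xj - xi) * (y - yi) - (yj - yi) * (x - xi))
    len <- abs(xj - xi) + abs(yj - yi)
    onb <- onb | (seg <= 1e-9 * (len + 1) &
                    x >= pmin(xi, xj) - 1e-12 & x <= pmax(xi, xj) + 1e-12 &
                    y >= pmin(yi, yj) - 1e-12 & y <= pmax(yi, yj) + 1e-12)
    j <- i
  }
  inside | onb
}

#' Synthetic habitat raster
#'
#' Generates a patchy categorical landscape by thresholding a stationary
#' Gaussian random field (squared-exponential correlation at
#' `clustering_scale`) at the empirical quantiles of the requested class
#' proportions, so realized proportions match the targets up to cell
#' rounding.  Stands in for a land-cover class grid when no real raster is
#' supplied.
#'
#' @param domain a `study_domain`; the raster covers its bounding box
#' @param cell_size cell edge length (km), > 0
#' @param class_proportions numeric simplex over the habitat classes
#'   (must sum to 1 within 1e-9); names, if present, become class labels
#' @param clustering_scale correlation length(s) of the underlying field
#'   (km).  A vector gives an equal-variance mixture of scales, e.g.
#'   `c(1, 20)` for a fine-grained mosaic embedded in large-scale
#'   cover gradients (the patch-size spectrum of real land-cover data)
#' @param class_labels labels for the H classes; defaults to the names of
#'   `class_proportions` or the standard five land-cover classes when H = 5
#' @param reference label of the reference class (density weight 1)
#' @param n_features number of random Fourier features approximating the field
#' @param seed optional integer seed (uses the global RNG stream if `NULL`)
#' @return object of class `habitat_raster`: `origin` (lower-left corner),
#'   `cell_size`, `nx`, `ny`, integer matrix `codes` (nx x ny, column j =
#'   northing row j, indexed from the lower-left, half-open cells),
#'   `class_labels`, `reference`.
#' @export
synthetic_landscape <- function(domain, cell_size, class_proportions,
                                clustering_scale, class_labels = NULL,
                                reference = "forest", n_features = 256L,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- class_proportions
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("`class_proportions` must be nonnegative and sum to 1 (within 1e-9)")
  }
  if (cell_size <= 0) stop("`cell_size` must be > 0")
  if (any(clustering_scale <= 0)) stop("`clustering_scale` must be > 0")
  H <- length(p)
  if (is.null(class_labels)) {
    class_labels <- names(p)
    if (is.null(class_labels)) {
      class_labels <- if (H == 5L) {
        c("artificial", "agricultural", "forest", "wetland", "water")
      } else paste0("class", seq_len(H))
    }
  }
  if (!reference %in% class_labels) {
    stop("`reference` must be one of the class labels")
  }
  bb <- domain$bbox
  nx <- ceiling((bb["xmax"] - bb["xmin"]) / cell_size)
  ny <- ceiling((bb["ymax"] - bb["ymin"]) / cell_size)
  if (nx < 1L || ny < 1L) stop("empty raster extent")
  cx <- bb["xmin"] + (seq_len(nx) - 0.5) * cell_size
  cy <- bb["ymin"] + (seq_len(ny) - 0.5) * cell_size
  f <- rff_field(rep(cx, times = ny), rep(cy, each = nx),
                 clustering_scale, n_features)
  # class thresholds at cumulative proportions of the realized field
  br <- stats::quantile(f, cumsum(p)[-H], names = FALSE, type = 7)
  codes <- findInterval(f, br, left.open = TRUE) + 1L
  structure(list(
    origin = c(x = unname(bb["xmin"]), y = unname(bb["ymin"])),
    cell_size = cell_size, nx = as.integer(nx), ny = as.integer(ny),
    codes = matrix(as.integer(codes), nx, ny),
    class_labels = class_labels, reference = reference
  ), class = "habitat_raster")
}

#' @export
print.habitat_raster <- function(x, ...) {
  cat(sprintf("Habitat raster: %d x %d cells of %.3g km, classes: %s (reference: %s)\n",
              x$nx, x$ny, x$cell_size,
              paste(x$class_labels, collapse = ", "), x$reference))
  invisible(x)
}

#' Uniform (single-class) raster
#'
#' Convenience constructor for a homogeneous landscape where every cell
#' carries the reference class, used by scenarios with no habitat structure.
#'
#' @inheritParams synthetic_landscape
#' @param class label of the single class filling the raster
#' @export
uniform_raster <- function(domain, cell_size = 10,
                           class_labels = "forest", reference = "forest",
                           class = reference) {
  bb <- domain$bbox
  nx <- max(1L, ceiling((bb["xmax"] - bb["xmin"]) / cell_size))
  ny <- max(1L, ceiling((bb["ymax"] - bb["ymin"]) / cell_size))
  code <- match(class, class_labels)
  if (is.na(code)) stop("`class` must be one of `class_labels`")
  structure(list(
    origin = c(x = unname(bb["xmin"]), y = unname(bb["ymin"])),
    cell_size = cell_size, nx = as.integer(nx), ny = as.integer(ny),
    codes = matrix(as.integer(code), nx, ny),
    class_labels = class_labels, reference = reference
  ), class = "habitat_raster")
}

# Random Fourier feature approximation of a Gaussian random field with
# squared-exponential correlation exp(-d^2 / (2 l^2)).  With several
# scales, features are split equally among them, giving an equal-variance
# mixture of correlation scales (a multi-scale patch mosaic).
rff_field <- function(x, y, scale, n_features) {
  m <- as.integer(n_features)
  sc <- rep_len(scale, m)  # cycles through the scales
  w1 <- stats::rnorm(m, 0, 1 / sc)
  w2 <- stats::rnorm(m, 0, 1 / sc)
  ph <- stats::runif(m, 0, 2 * pi)
  f <- numeric(length(x))
  for (k in seq_len(m)) {
    f <- f + cos(w1[k] * x + w2[k] * y + ph[k])
  }
  f * sqrt(2 / m)
}

#' Habitat class at points
#'
#' Looks up the habitat class of the cell containing each point.  Cells are
#' half-open, `[x0, x0 + cell) x [y0, y0 + cell)`, so a point on a shared
#' edge belongs to the higher-index cell.
#'
#' @param raster a `habitat_raster`
#' @param x,y point coordinates (km); must fall inside the raster extent
#' @return integer vector of class codes
#' @export
habitat_at <- function(raster, x, y) {
  ix <- floor((x - raster$origin[["x"]]) / raster$cell_size) + 1
  iy <- floor((y - raster$origin[["y"]]) / raster$cell_size) + 1
  bad <- ix < 1 | ix > raster$nx | iy < 1 | iy > raster$ny
  if (any(bad, na.rm = TRUE) || anyNA(bad)) {
    stop("point(s) outside the raster extent")
  }
  raster$codes[cbind(as.integer(ix), as.integer(iy))]
}

#' Cell centres of a raster
#' @param raster a `habitat_raster`
#' @return data frame with `x`, `y` (cell centres, km) and `class` code,
#'   in column-major (row of constant northing first) order
#' @export
raster_cell_centers <- function(raster) {
  cs <- raster$cell_size
  cx <- raster$origin[["x"]] + (seq_len(raster$nx) - 0.5) * cs
  cy <- raster$origin[["y"]] + (seq_len(raster$ny) - 0.5) * cs
  data.frame(x = rep(cx, times = raster$ny),
             y = rep(cy, each = raster$nx),
             class = as.vector(raster$codes))
}

#' Habitat class areas within a domain
#'
#' Area of each habitat class, counting cells whose centre lies inside the
#' domain polygon.
#'
#' @param raster a `habitat_raster`
#' @param domain optional `study_domain` clipping the raster
#' @return named numeric vector of areas (km^2) per class label
#' @export
raster_class_areas <- function(raster, domain = NULL) {
  cc <- raster_cell_centers(raster)
  if (!is.null(domain)) {
    cc <- cc[domain_contains(domain, cc$x, cc$y), , drop = FALSE]
  }
  cnt <- tabulate(cc$class, nbins = length(raster$class_labels))
  stats::setNames(cnt * raster$cell_size^2, raster$class_labels)
}

#' Habitat-weighted area
#'
#' \eqn{\sum_i h_i A_i} over the habitat classes, the effective area used to
#' convert a reference-habitat density into a total population size.
#'
#' @param raster a `habitat_raster`
#' @param weights named vector of relative habitat weights `h` (reference
#'   class weight 1); must cover every class present
#' @param domain optional clipping `study_domain`
#' @return weighted area (km^2)
#' @export
habitat_weighted_area <- function(raster, weights, domain = NULL) {
  a <- raster_class_areas(raster, domain)
  miss <- setdiff(names(a)[a > 0], names(weights))
  if (length(miss)) stop("no habitat weight for class(es): ",
                         paste(miss, collapse = ", "))
  sum(a * weights[names(a)], na.rm = TRUE)
}

#' Write / read a habitat raster as an ESRI ASCII grid
#'
#' Plain-text single-band grid of integer class codes.  Class labels and the
#' reference class are stored as `#` comment lines after the header, so a
#' round trip preserves them; rasters written by other software can supply
#' them via arguments.
#'
#' @param raster a `habitat_raster`
#' @param file path
#' @export
write_asc <- function(raster, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", raster$nx),
    sprintf("nrows %d", raster$ny),
    sprintf("xllcorner %.10g", raster$origin[["x"]]),
    sprintf("yllcorner %.10g", raster$origin[["y"]]),
    sprintf("cellsize %.10g", raster$cell_size),
    "NODATA_value -9999",
    paste("# class_labels", paste(raster$class_labels, collapse = " ")),
    paste("# reference", raster$reference)
  ), con)
  # ASCII grids store rows north-to-south
  for (j in rev(seq_len(raster$ny))) {
    writeLines(paste(raster$codes[, j], collapse = " "), con)
  }
  invisible(file)
}

#' @rdname write_asc
#' @param class_labels,reference overrides when the file carries no metadata
#' @export
read_asc <- function(file, class_labels = NULL, reference = NULL) {
  ln <- readLines(file)
  hdr <- list()
  i <- 1L
  while (grepl("^[a-zA-Z#]", ln[i])) {
    parts <- strsplit(trimws(ln[i]), "\\s+")[[1]]
    if (parts[1] == "#") {
      hdr[[parts[2]]] <- parts[-(1:2)]
    } else {
      hdr[[tolower(parts[1])]] <- parts[2]
    }
    i <- i + 1L
  }
  nx <- as.integer(hdr$ncols); ny <- as.integer(hdr$nrows)
  vals <- scan(text = paste(ln[i:length(ln)], collapse = "\n"), quiet = TRUE)
  codes <- matrix(as.integer(vals), nrow = nx)  # columns are N->S rows
  codes <- codes[, rev(seq_len(ny)), drop = FALSE]
  labels <- class_labels %||% hdr$class_labels %||%
    paste0("class", seq_len(max(codes)))
  structure(list(
    origin = c(x = as.numeric(hdr$xllcorner), y = as.numeric(hdr$yllcorner)),
    cell_size = as.numeric(hdr$cellsize), nx = nx, ny = ny, codes = codes,
    class_labels = labels,
    reference = reference %||% (hdr$reference %||% labels[1])
  ), class = "habitat_raster")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Domain polygon as WKT
#'
#' Serializes a study domain's boundary as a Well-Known Text POLYGON (and
#' back), for exchange with GIS tools.  Coordinates stay in planar km.
#'
#' @param domain a `study_domain`
#' @return a WKT `POLYGON` string
#' @export
domain_to_wkt <- function(domain) {
  v <- rbind(domain$boundary, domain$boundary[1, ])
  sprintf("POLYGON ((%s))",
          paste(sprintf("%.10g %.10g", v[, 1], v[, 2]), collapse = ", "))
}

#' @rdname domain_to_wkt
#' @param wkt a WKT `POLYGON` string (single outer ring)
#' @export
domain_from_wkt <- function(wkt) {
  inner <- regmatches(wkt, regexpr("\\(\\([^)]*\\)\\)", wkt))
  if (!length(inner)) stop("not a WKT POLYGON")
  nums <- strsplit(trimws(strsplit(gsub("[()]", "", inner), ",")[[1]]),
                   "\\s+")
  xy <- do.call(rbind, lapply(nums, function(p) as.numeric(p[1:2])))
  study_domain(xy)
}
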
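#' Build a triangular survey transect
#'
#' Equilateral triangle of the winter track count design: side 4 km,
#' perimeter 12 km, centred at its centroid with one vertex at angle
#' `rotation`.
#'
#' @param center centroid (x, y) in km
#' @param rotation angle (radians) of the first vertex
#' @param side side length (km), > 0
#' @return object of class `transect` with `vertices` (3 x 2 matrix),
#'   `center`, `rotation`, `side`, and mutable survey fields `counting_day`
#'   and `D_days` (accumulation period, default 1 day)
#' @export
build_triangle <- function(center, rotation = 0, side = 4) {
  if (side <= 0) stop("`side` must be > 0")
  r <- side / sqrt(3)  # circumradius
  ang <- rotation + c(0, 2, 4) * pi / 3
  structure(list(
    vertices = cbind(x = center[1] + r * cos(ang),
                     y = center[2] + r * sin(ang)),
    center = c(x = unname(center[1]), y = unname(center[2])),
    rotation = rotation, side = side,
    counting_day = NA_integer_, D_days = 1
  ), class = "transect")
}

#' @export
print.transect <- function(x, ...) {
  cat(sprintf("Transect: equilateral triangle, side %g km, centre (%.1f, %.1f)\n",
              x$side, x$center[1], x$center[2]))
  invisible(x)
}

#' Generate the transect network
#'
#' Places `n` triangles with uniformly random centres (inside the domain)
#' and rotations.  When `min_reference_fraction > 0`, candidate placements
#' are rejection-sampled until at least that fraction of the in-domain
#' perimeter lies on the reference habitat class, emulating the forest-
#' biased placement of the real survey.
#'
#' @param n number of transects (full design: 1610)
#' @param domain a `study_domain`
#' @param raster a `habitat_raster` (needed when
#'   `min_reference_fraction > 0`)
#' @param min_reference_fraction minimum perimeter fraction on the reference
#'   class (0 disables the constraint)
#' @param side triangle side (km)
#' @param spacing perimeter sampling interval (km) for the habitat check
#' @param max_tries total rejection cap
#' @return list of `transect` objects (ids = list position)
#' @export
generate_transect_network <- function(n, domain, raster = NULL,
                                      min_reference_fraction = 0, side = 4,
                                      spacing = 0.025, max_tries = 100000L) {
  bb <- domain$bbox
  ref_code <- if (!is.null(raster)) {
    match(raster$reference, raster$class_labels)
  } else NA_integer_
  if (min_reference_fraction > 0 && is.null(raster)) {
    stop("`raster` with a reference class is required when ",
         "`min_reference_fraction` > 0")
  }
  out <- vector("list", n)
  made <- 0L
  for (k in seq_len(max_tries)) {
    cx <- stats::runif(1, bb["xmin"], bb["xmax"])
    cy <- stats::runif(1, bb["ymin"], bb["ymax"])
    if (!domain_contains(domain, cx, cy)) next
    tr <- build_triangle(c(cx, cy), stats::runif(1, 0, 2 * pi), side)
    if (min_reference_fraction > 0) {
      pp <- perimeter_points(tr, spacing)
      ins <- domain_contains(domain, pp$x, pp$y)
      if (!any(ins)) next
      frac <- mean(habitat_at(raster, pp$x[ins], pp$y[ins]) == ref_code)
      if (frac < min_reference_fraction) next
    }
    made <- made + 1L
    tr$id <- made
    out[[made]] <- tr
    if (made == n) return(out)
  }
  stop("transect rejection cap exceeded: landscape has too little ",
       "reference habitat")
}

#' Draw the transects surveyed in one year
#'
#' A uniform subset of `n_surveyed` transects without replacement, each
#' given a counting day uniform on 1..`season_days` and (optionally) a
#' freshly randomized rotation.
#'
#' @param network list of `transect`s
#' @param n_surveyed transects surveyed that year (full design: 500)
#' @param season_days length of the counting season (days)
#' @param redraw_rotation redraw each surveyed transect's rotation?
#' @return list of surveyed `transect`s with `counting_day` set
#' @export
sample_survey_year <- function(network, n_surveyed, season_days = 60,
                               redraw_rotation = TRUE) {
  if (n_surveyed > length(network)) {
    stop("`n_surveyed` exceeds the network size")
  }
  idx <- sample.int(length(network), n_surveyed)
  lapply(idx, function(i) {
    tr <- network[[i]]
    if (redraw_rotation) {
      tr <- build_triangle(tr$center, stats::runif(1, 0, 2 * pi), tr$side)
      tr$id <- network[[i]]$id
    }
    tr$counting_day <- sample.int(season_days, 1)
    tr
  })
}

# Vectorized segment intersection: segments (x1,y1)-(x2,y2) against one
# segment (x3,y3)-(x4,y4).  Endpoint touching and grazing tangency count as
# an intersection; collinear overlap counts as one.
segments_cross <- function(x1, y1, x2, y2, x3, y3, x4, y4) {
  d1 <- (x4 - x3) * (y1 - y3) - (y4 - y3) * (x1 - x3)
  d2 <- (x4 - x3) * (y2 - y3) - (y4 - y3) * (x2 - x3)
  d3 <- (x2 - x1) * (y3 - y1) - (y2 - y1) * (x3 - x1)
  d4 <- (x2 - x1) * (y4 - y1) - (y2 - y1) * (x4 - x1)
  proper <- ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
  on12 <- function(px, py) {  # collinear point on segment 1-2?
    px >= pmin(x1, x2) & px <= pmax(x1, x2) &
      py >= pmin(y1, y2) & py <= pmax(y1, y2)
  }
  on34 <- function(px, py) {
    px >= pmin(x3, x4) & px <= pmax(x3, x4) &
      py >= pmin(y3, y4) & py <= pmax(y3, y4)
  }
  touch <- (d1 == 0 & on34(x1, y1)) | (d2 == 0 & on34(x2, y2)) |
    (d3 == 0 & on12(x3, y3)) | (d4 == 0 & on12(x4, y4))
  proper | touch
}

#' Count track crossings on a transect
#'
#' Counts intersections between animal movement segments within the 24-hour
#' accumulation window of the transect's counting day and the triangle's
#' edges.  The window comprises the six 4-h steps of the counting day
#' (ending at midnight).  Each geometric intersection contributes the
#' agent's group size to the count, under the convention that group members
#' travel together and each leaves a track.
#'
#' @param traj a `trajectories` object
#' @param transect a `transect` (its `counting_day` is used unless `day`
#'   is given)
#' @param day counting day override (1-based)
#' @param count_groups multiply intersections by group size? (default TRUE)
#' @return integer count \eqn{X_{it}}
#' @export
count_crossings <- function(traj, transect, day = transect$counting_day,
                            count_groups = TRUE) {
  if (is.na(day)) stop("transect has no counting day")
  steps_per_day <- round(1 / diff(traj$t_days[1:2]))
  i0 <- (day - 1L) * steps_per_day + 1L
  i1 <- min(day * steps_per_day + 1L, nrow(traj$x))
  if (i1 <= i0) stop("trajectories do not cover the counting window")
  v <- transect$vertices
  n <- ncol(traj$x)
  hits <- integer(n)
  for (s in i0:(i1 - 1L)) {
    ax <- traj$x[s, ]; ay <- traj$y[s, ]
    bx <- traj$x[s + 1L, ]; by <- traj$y[s + 1L, ]
    for (e in 1:3) {
      f <- if (e == 3L) 1L else e + 1L
      hits <- hits + segments_cross(ax, ay, bx, by,
                                    v[e, 1], v[e, 2], v[f, 1], v[f, 2])
    }
  }
  w <- if (count_groups) traj$group_size else rep(1L, n)
  as.integer(sum(hits * w))
}

# Midpoint sample of a transect perimeter at roughly `spacing` km,
# returning point coordinates and the represented length per point.
perimeter_points <- function(transect, spacing = 0.025) {
  v <- transect$vertices
  xs <- ys <- wl <- NULL
  for (e in 1:3) {
    f <- if (e == 3L) 1L else e + 1L
    len <- sqrt(sum((v[f, ] - v[e, ])^2))
    m <- max(1L, ceiling(len / spacing))
    tt <- (seq_len(m) - 0.5) / m
    xs <- c(xs, v[e, 1] + tt * (v[f, 1] - v[e, 1]))
    ys <- c(ys, v[e, 2] + tt * (v[f, 2] - v[e, 2]))
    wl <- c(wl, rep(len / m, m))
  }
  list(x = xs, y = ys, len = wl)
}

#' Per-habitat perimeter lengths of a transect
#'
#' Length of transect perimeter lying on each habitat class and inside the
#' study domain, measured by sampling the perimeter at `spacing` km
#' (default 25 m, the land-cover grid scale).
#'
#' @param transect a `transect`
#' @param raster a `habitat_raster`
#' @param domain a `study_domain`
#' @param spacing perimeter sampling interval (km)
#' @return named vector of in-domain lengths (km) per class label
#' @export
perimeter_by_habitat <- function(transect, raster, domain, spacing = 0.025) {
  pp <- perimeter_points(transect, spacing)
  ins <- domain_contains(domain, pp$x, pp$y)
  H <- length(raster$class_labels)
  out <- numeric(H)
  if (any(ins)) {
    cls <- habitat_at(raster, pp$x[ins], pp$y[ins])
    out <- vapply(seq_len(H), function(cc) sum(pp$len[ins][cls == cc]),
                  numeric(1))
  }
  stats::setNames(out, raster$class_labels)
}

#' Habitat-weighted effective transect effort
#'
#' \eqn{M_{it} = \sum_{\mathrm{habitats}} (\mathrm{perimeter\ length\ in\
#' habitat}) \times h_{\mathrm{habitat}}}; perimeter outside the study
#' domain contributes nothing.
#'
#' @inheritParams perimeter_by_habitat
#' @param weights named habitat weights (reference class weight 1)
#' @return effective effort `M` (km); 0 when fully outside the domain
#' @export
effective_effort <- function(transect, raster, weights, domain,
                             spacing = 0.025) {
  lens <- perimeter_by_habitat(transect, raster, domain, spacing)
  wcode <- weights_by_code(raster, weights)
  sum(lens * wcode)
}

#' Survey one simulated year
#'
#' Applies the yearly survey protocol to a season of trajectories: draws
#' the surveyed subset of the network, counts crossings in each transect's
#' 24-hour window and measures in-domain perimeter length per habitat
#' class.  Habitat weighting of the effort happens later, via
#' [apply_effort_weights()], because with real data the weights are only
#' estimated after the survey.  Transects fully outside the domain are
#' excluded.
#'
#' @param traj season `trajectories`
#' @param network transect network (list of `transect`s)
#' @param n_surveyed transects surveyed this year
#' @param raster,domain passed to [perimeter_by_habitat()]
#' @param year year index stamped on the records
#' @param redraw_rotation redraw rotations (yearly protocol)?
#' @param spacing perimeter sampling interval (km)
#' @return data frame of count records: `transect_id`, `year`, `count`,
#'   `counting_day`, `D_days`, `x`, `y`, and one `len_<class>` column per
#'   habitat class
#' @export
survey_year <- function(traj, network, n_surveyed, raster, domain,
                        year = 1L, redraw_rotation = TRUE, spacing = 0.025) {
  surveyed <- sample_survey_year(network, n_surveyed,
                                 season_days = floor(max(traj$t_days)),
                                 redraw_rotation = redraw_rotation)
  rec <- lapply(surveyed, function(tr) {
    lens <- perimeter_by_habitat(tr, raster, domain, spacing)
    if (sum(lens) <= 0) return(NULL)
    d <- data.frame(transect_id = tr$id, year = year,
                    count = count_crossings(traj, tr),
                    counting_day = tr$counting_day, D_days = tr$D_days,
                    x = unname(tr$center[1]), y = unname(tr$center[2]))
    d[paste0("len_", names(lens))] <- as.list(unname(lens))
    d
  })
  do.call(rbind, rec)
}

#' Apply habitat weights to survey effort
#'
#' Computes the effective effort column `M_km` of a count-record table from
#' its per-habitat perimeter lengths: \eqn{M = \sum_c h_c \ell_c}.
#'
#' @param records output of [survey_year()] (possibly several years)
#' @param weights named habitat weights
#' @return `records` with an `M_km` column added (zero-effort rows dropped)
#' @export
apply_effort_weights <- function(records, weights) {
  lcols <- grep("^len_", names(records), value = TRUE)
  cls <- sub("^len_", "", lcols)
  miss <- setdiff(cls, names(weights))
  if (length(miss)) stop("no habitat weight for class(es): ",
                         paste(miss, collapse = ", "))
  records$M_km <- as.matrix(records[lcols]) %*% weights[cls]
  records$M_km <- as.numeric(records$M_km)
  records[records$M_km > 0, , drop = FALSE]
}
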
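#' Choose individuals to collar
#'
#' Uniform sample without replacement of `n` agents per year (all agents
#' when fewer than `n` are alive).
#'
#' @param agents agent data frame
#' @param n collars available (default 10)
#' @return vector of collared agent ids
#' @export
collar_individuals <- function(agents, n = 10) {
  if (nrow(agents) < 1L) stop("empty population")
  agents$id[sample.int(nrow(agents), min(n, nrow(agents)))]
}

#' Extract GPS bursts from trajectories
#'
#' One burst is one individual's fix series over the survey season.
#'
#' @param traj a `trajectories` object
#' @param ids agent ids to extract (default all)
#' @param year optional year stamp carried on each burst
#' @return list of `gps_burst` objects: `x`, `y`, `t_days`, `id`, `year`
#' @export
trajectories_to_bursts <- function(traj, ids = traj$id, year = NA_integer_) {
  lapply(ids, function(i) {
    j <- match(i, traj$id)
    structure(list(x = traj$x[, j], y = traj$y[, j], t_days = traj$t_days,
                   id = i, year = year), class = "gps_burst")
  })
}

#' Read GPS fixes from a data frame
#'
#' Converts a fix table (`individual_id`, `t_days`, `x_km`, `y_km`) into a
#' list of bursts, one per individual, time-ordered.
#'
#' @param fixes data frame of GPS fixes
#' @export
bursts_from_fixes <- function(fixes) {
  lapply(split(fixes, fixes$individual_id), function(d) {
    d <- d[order(d$t_days), ]
    structure(list(x = d$x_km, y = d$y_km, t_days = d$t_days,
                   id = d$individual_id[1], year = NA_integer_),
              class = "gps_burst")
  })
}

#' Mean daily movement distance E[L]
#'
#' Averages the path distance accumulated within each 24-hour day (the sum
#' of consecutive-fix distances) over all full days and all bursts.
#'
#' @param bursts list of `gps_burst`s
#' @return E[L] in km/day
#' @export
estimate_daily_distance <- function(bursts) {
  if (!length(bursts)) stop("no bursts supplied")
  daily <- unlist(lapply(bursts, function(b) {
    sl <- sqrt(diff(b$x)^2 + diff(b$y)^2)
    day <- ceiling(b$t_days[-1] - 1e-9)  # day of each step's end fix
    steps_per_day <- round(1 / diff(b$t_days[1:2]))
    nd <- max(day)
    full <- tabulate(day, nbins = nd)
    agg <- tapply(sl, factor(day, levels = seq_len(nd)), sum)
    agg[full == steps_per_day]  # only complete days
  }))
  if (!length(daily)) stop("no complete days in the bursts")
  mean(daily)
}

# Step decomposition of a burst: step j joins fixes j and j+1; the turning
# angle (change of bearing) is defined from step 2 onwards.
burst_steps <- function(burst) {
  dx <- diff(burst$x); dy <- diff(burst$y)
  len <- sqrt(dx^2 + dy^2)
  bearing <- atan2(dy, dx)
  turn <- c(NA_real_, diff(bearing))
  data.frame(len = len, bearing = bearing, turn = turn)
}

#' Null movement steps for a burst
#'
#' For each realized step (from step 2 on, where a turning angle is
#' defined), draws `n_null` alternative endpoints from the step's start
#' point using turning angles and step lengths resampled independently from
#' the burst's own empirical distributions.  Endpoints falling outside the
#' domain are redrawn, so availability reflects accessible habitat.
#'
#' @param burst a `gps_burst`
#' @param domain a `study_domain` (NULL disables the boundary redraw)
#' @param n_null null steps per realized step (default 30)
#' @param max_tries redraw cap
#' @return list with matrices `x`, `y` (rows = steps 2..J, cols = null
#'   draws) and the row index `step`
#' @export
generate_null_steps <- function(burst, domain = NULL, n_null = 30,
                                max_tries = 10000L) {
  st <- burst_steps(burst)
  J <- nrow(st)
  if (J < 2L) stop("burst has fewer than 2 steps")
  turns <- st$turn[-1L]
  lens <- st$len
  if (all(lens == 0)) stop("degenerate burst: all fixes identical")
  rows <- 2:J
  m <- length(rows) * n_null
  x0 <- rep(burst$x[rows], n_null)      # start point of step j = fix j
  y0 <- rep(burst$y[rows], n_null)
  h0 <- rep(st$bearing[rows - 1L], n_null)  # bearing of previous step
  px <- py <- numeric(m)
  need <- seq_len(m)
  for (k in seq_len(max_tries)) {
    nn <- length(need)
    hh <- h0[need] + sample(turns, nn, replace = TRUE)
    ll <- sample(lens, nn, replace = TRUE)
    qx <- x0[need] + ll * cos(hh)
    qy <- y0[need] + ll * sin(hh)
    ok <- if (is.null(domain)) rep(TRUE, nn) else domain_contains(domain, qx, qy)
    px[need[ok]] <- qx[ok]
    py[need[ok]] <- qy[ok]
    need <- need[!ok]
    if (!length(need)) {
      return(list(x = matrix(px, ncol = n_null),
                  y = matrix(py, ncol = n_null), step = rows))
    }
  }
  stop("null-step redraw cap exceeded")
}

#' Used and available habitat proportions for one burst
#'
#' `p_ik` is the fraction of realized step endpoints in habitat class `i`;
#' `q_ik` is the mean fraction of null-step endpoints in class `i`.  Both
#' are partitions (each sums to 1 over classes).
#'
#' @param burst a `gps_burst`
#' @param raster a `habitat_raster`
#' @param null_steps output of [generate_null_steps()] for this burst
#' @return list with named vectors `p` and `q` and the step count `J`
#' @export
burst_usage <- function(burst, raster, null_steps) {
  H <- length(raster$class_labels)
  rows <- null_steps$step
  used <- habitat_at(raster, burst$x[rows + 1L], burst$y[rows + 1L])
  p <- tabulate(used, nbins = H) / length(used)
  nullc <- habitat_at(raster, as.vector(null_steps$x),
                      as.vector(null_steps$y))
  q <- tabulate(nullc, nbins = H) / length(nullc)
  list(p = stats::setNames(p, raster$class_labels),
       q = stats::setNames(q, raster$class_labels), J = length(rows))
}

#' Pooled habitat preferences
#'
#' The ratio-of-pooled-sums estimator
#' \eqn{w_i = \sum_k p_{ik} / \sum_k q_{ik}} (not a mean of per-burst
#' ratios).  Classes never available across bursts (pooled q = 0) are
#' returned as `NA` (undefined), not 0.
#'
#' @param usages list of [burst_usage()] results
#' @return named vector of preferences `w`
#' @export
pooled_preferences <- function(usages) {
  P <- Reduce(`+`, lapply(usages, `[[`, "p"))
  Q <- Reduce(`+`, lapply(usages, `[[`, "q"))
  w <- ifelse(Q > 0, P / Q, NA_real_)
  stats::setNames(w, names(P))
}

#' Habitat weights relative to the reference class
#'
#' \eqn{h_i = w_i / w_{\mathrm{ref}}} with \eqn{h_{\mathrm{ref}} = 1}
#' exactly.
#'
#' @param w preference vector from [pooled_preferences()]
#' @param reference reference class label
#' @return named vector of weights `h`
#' @export
relative_weights <- function(w, reference) {
  if (!reference %in% names(w)) stop("unknown reference class")
  wr <- w[[reference]]
  if (is.na(wr) || wr <= 0) stop("reference class preference is zero or undefined")
  h <- w / wr
  h[[reference]] <- 1
  h
}

#' Estimate habitat weights from GPS bursts
#'
#' Full step-selection pipeline: null steps, per-burst usage, pooled
#' preferences, weights relative to the reference class.
#'
#' @param bursts list of `gps_burst`s
#' @param raster a `habitat_raster`
#' @param domain a `study_domain`
#' @param n_null null steps per realized step
#' @return list with `h` (weights), `w` (preferences), and the per-burst
#'   `usages` (for diagnostics or bootstrapping)
#' @export
habitat_weights <- function(bursts, raster, domain, n_null = 30) {
  usages <- lapply(bursts, function(b) {
    ns <- generate_null_steps(b, domain, n_null)
    burst_usage(b, raster, ns)
  })
  w <- pooled_preferences(usages)
  list(h = relative_weights(w, raster$reference), w = w, usages = usages)
}

#' Bootstrap intervals for habitat weights
#'
#' Resamples bursts with replacement and recomputes the pooled weights;
#' percentile intervals at `level`.
#'
#' @param usages per-burst usage list (from [habitat_weights()]`$usages`)
#' @param reference reference class label
#' @param n_boot bootstrap resamples
#' @param level interval level
#' @return matrix with rows `lo`, `hi` and one column per class
#' @export
bootstrap_habitat_weights <- function(usages, reference, n_boot = 1000,
                                      level = 0.95) {
  K <- length(usages)
  hs <- replicate(n_boot, {
    idx <- sample.int(K, K, replace = TRUE)
    w <- pooled_preferences(usages[idx])
    relative_weights(w, reference)
  })
  apply(hs, 1, stats::quantile,
        probs = c((1 - level) / 2, (1 + level) / 2), na.rm = TRUE)
}
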
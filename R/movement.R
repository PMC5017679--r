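#' Movement model configuration
#'
#' Parameters of the correlated random walk (CRW) and its scenario
#' extensions.  Defaults reproduce the simulation study's movement law:
#' 4-hour steps, wrapped-normal turning angles with mean resultant length
#' (circular correlation) 0.70, Weibull(shape 2, scale 2 km) step lengths
#' (hence mean daily path length 6 * 2 * Gamma(1.5) = 10.63 km), 90 %
#' territorial individuals biased 30 % towards their territory centre beyond
#' 10 km, 10 candidate steps for habitat selection, and group sizes
#' 1 + Poisson(4).
#'
#' @param step_hours time step (h)
#' @param turn_correlation mean resultant length of the wrapped-normal
#'   turning-angle distribution, in [0, 1)
#' @param step_shape,step_scale Weibull parameters of the per-step length (km)
#' @param territorial_fraction yearly fraction of territorial agents
#' @param bias_weight probability that a territorial agent's step heads
#'   straight to its territory centre when beyond `territory_radius`
#' @param territory_radius distance (km) beyond which the bias applies
#' @param n_candidates candidate steps for habitat-selective movement
#' @param group_mean_extra Poisson mean of group size minus one
#' @param max_tries retry cap for boundary / habitat rejection sampling
#' @return list of class `movement_config`
#' @export
movement_config <- function(step_hours = 4, turn_correlation = 0.70,
                            step_shape = 2, step_scale = 2,
                            territorial_fraction = 0.90, bias_weight = 0.30,
                            territory_radius = 10, n_candidates = 10L,
                            group_mean_extra = 4, max_tries = 10000L) {
  stopifnot(turn_correlation >= 0, turn_correlation < 1,
            bias_weight >= 0, bias_weight <= 1,
            step_shape > 0, step_scale > 0, step_hours > 0,
            territory_radius > 0, n_candidates >= 1)
  structure(list(step_hours = step_hours, turn_correlation = turn_correlation,
                 step_shape = step_shape, step_scale = step_scale,
                 territorial_fraction = territorial_fraction,
                 bias_weight = bias_weight, territory_radius = territory_radius,
                 n_candidates = as.integer(n_candidates),
                 group_mean_extra = group_mean_extra,
                 max_tries = as.integer(max_tries)),
            class = "movement_config")
}

#' Demographic (environmental stochasticity) configuration
#'
#' The yearly population growth-rate expectation \eqn{\mu} is drawn from a
#' log-normal distribution; the defaults (log-mean 0, log-sd 0.1) keep the
#' expected population size constant while placing 95 % of yearly growth
#' rates within about [0.82, 1.22].
#'
#' @param env_log_mean,env_log_sd parameters of the underlying normal
#' @export
demography_config <- function(env_log_mean = 0, env_log_sd = 0.1) {
  stopifnot(env_log_sd >= 0)
  structure(list(env_log_mean = env_log_mean, env_log_sd = env_log_sd),
            class = "demography_config")
}

#' Simulation scenario specification
#'
#' Six scenarios combine four deviations from the baseline CRW in a
#' homogeneous landscape: \describe{
#'   \item{A}{plain CRW, uniform initial distribution, solitary agents}
#'   \item{B}{A + territorial movement (90 % of agents biased home)}
#'   \item{C}{A + agents are groups of 1 + Poisson(4) individuals}
#'   \item{D}{A + heterogeneous initial distribution, intensity
#'     proportional to exp(F) with F a Matern field (scale 100 km,
#'     variance 16)}
#'   \item{E}{A + habitat-selective movement and initial distribution,
#'     with true weights forest 1, wetland 0.50, agricultural and
#'     artificial 0.10, water 0.05}
#'   \item{F}{B + C + D + E combined}
#' }
#'
#' @param code scenario letter, "A".."F"
#' @param initial_n initial number of agents (solitary scenarios, default
#'   200) or groups (grouped scenarios, default 40)
#' @param habitat_weights_true named vector of true relative habitat
#'   weights used by habitat-selective scenarios
#' @param init_field_scale,init_field_variance Matern parameters of the
#'   initial-intensity field used by scenarios D and F
#' @return list of class `scenario_spec` with logical flags `territorial`,
#'   `grouped`, `habitat_selection`, `hetero_init`
#' @export
scenario_spec <- function(code = c("A", "B", "C", "D", "E", "F"),
                          initial_n = NULL,
                          habitat_weights_true = c(artificial = 0.10,
                                                   agricultural = 0.10,
                                                   forest = 1,
                                                   wetland = 0.50,
                                                   water = 0.05),
                          init_field_scale = 100, init_field_variance = 16) {
  code <- match.arg(code)
  grouped <- code %in% c("C", "F")
  if (is.null(initial_n)) initial_n <- if (grouped) 40L else 200L
  structure(list(code = code,
                 initial_n = as.integer(initial_n),
                 territorial = code %in% c("B", "F"),
                 grouped = grouped,
                 habitat_selection = code %in% c("E", "F"),
                 hetero_init = code %in% c("D", "F"),
                 habitat_weights_true = habitat_weights_true,
                 init_field_scale = init_field_scale,
                 init_field_variance = init_field_variance),
            class = "scenario_spec")
}

#' Wrapped-normal turning angles
#'
#' Draws turning angles whose wrapped-normal distribution has mean resultant
#' length (circular correlation) `rho`; the underlying normal has standard
#' deviation \eqn{\sqrt{-2\log\rho}}.
#'
#' @param n number of draws
#' @param rho circular correlation in [0, 1); `rho = 1` returns zeros
#' @export
rwrapped_normal <- function(n, rho) {
  if (rho >= 1) return(numeric(n))
  stats::rnorm(n, 0, sqrt(-2 * log(rho)))
}

#' Propose correlated-random-walk steps
#'
#' One CRW proposal per agent: new heading = old heading + wrapped-normal
#' turn, displacement length Weibull.  No boundary or habitat screening.
#'
#' @param agents agent data frame with columns `x`, `y`, `heading`
#' @param cfg a [movement_config()]
#' @return data frame with proposed `x`, `y`, `heading`, `length`
#' @export
draw_crw_step <- function(agents, cfg = movement_config()) {
  n <- nrow(agents)
  h <- agents$heading + rwrapped_normal(n, cfg$turn_correlation)
  len <- stats::rweibull(n, cfg$step_shape, cfg$step_scale)
  data.frame(x = agents$x + len * cos(h), y = agents$y + len * sin(h),
             heading = h, length = len)
}

#' Territorial heading bias
#'
#' For territorial agents farther than `territory_radius` from their
#' territory centre, the proposed heading is replaced, with probability
#' `bias_weight`, by the bearing to the centre; all other agents keep the
#' CRW proposal.
#'
#' @param agents agent data frame with `x`, `y`, `tx`, `ty`, `territorial`
#' @param heading proposed headings (radians), one per agent
#' @param cfg a [movement_config()]
#' @return adjusted headings
#' @export
apply_territorial_bias <- function(agents, heading, cfg = movement_config()) {
  if (any(agents$territorial & (is.na(agents$tx) | is.na(agents$ty)))) {
    stop("territorial agent without a territory centre")
  }
  d2 <- (agents$x - agents$tx)^2 + (agents$y - agents$ty)^2
  far <- agents$territorial & d2 > cfg$territory_radius^2
  repl <- far & stats::runif(nrow(agents)) < cfg$bias_weight
  if (any(repl)) {
    heading[repl] <- atan2(agents$ty[repl] - agents$y[repl],
                           agents$tx[repl] - agents$x[repl])
  }
  heading
}

#' Rejection sampling against the domain boundary
#'
#' Movements that would cross the domain boundary are discarded and new
#' candidate locations drawn until the first one inside is found (reflecting
#' boundary in the rejection sense).  Vectorized over `n` independent slots.
#'
#' @param domain a `study_domain`
#' @param propose `function(m)` returning a list/data frame with numeric
#'   `x` and `y` of length `m` (extra elements are carried through)
#' @param n number of accepted locations needed
#' @param max_tries retry cap; exceeding it signals degenerate geometry
#' @return data frame of `n` accepted proposals (all columns of `propose`)
#' @export
enforce_boundary <- function(domain, propose, n, max_tries = 10000L) {
  out <- NULL
  need <- seq_len(n)
  for (k in seq_len(max_tries)) {
    p <- as.data.frame(propose(length(need)))
    if (is.null(out)) out <- p[rep(1L, n), , drop = FALSE]
    ok <- domain_contains(domain, p$x, p$y)
    if (any(ok)) out[need[ok], ] <- p[ok, , drop = FALSE]
    need <- need[!ok]
    if (!length(need)) {
      rownames(out) <- NULL
      return(out)
    }
  }
  stop("boundary rejection cap exceeded (degenerate geometry?)")
}

# One synchronous movement step for all agents.  Habitat-selective scenarios
# draw `n_candidates` CRW proposals per agent and pick one with probability
# proportional to the habitat weight at its endpoint (out-of-domain
# candidates get weight 0); otherwise a single proposal is redrawn until it
# falls inside the domain.
step_agents <- function(agents, spec, domain, raster, wcode, cfg) {
  n <- nrow(agents)
  resx <- resy <- resh <- numeric(n)
  need <- seq_len(n)
  C <- if (spec$habitat_selection) cfg$n_candidates else 1L
  for (k in seq_len(cfg$max_tries)) {
    m <- length(need)
    mc <- m * C
    hh <- rep(agents$heading[need], C) + rwrapped_normal(mc, cfg$turn_correlation)
    if (spec$territorial) {
      sub <- agents[rep(need, C), c("x", "y", "tx", "ty", "territorial")]
      hh <- apply_territorial_bias(sub, hh, cfg)
    }
    len <- stats::rweibull(mc, cfg$step_shape, cfg$step_scale)
    px <- rep(agents$x[need], C) + len * cos(hh)
    py <- rep(agents$y[need], C) + len * sin(hh)
    w <- numeric(mc)
    ok <- domain_contains(domain, px, py)
    if (spec$habitat_selection) {
      w[ok] <- wcode[habitat_at(raster, px[ok], py[ok])]
    } else {
      w[ok] <- 1
    }
    # Gumbel-max trick: weighted choice among candidates, rowwise
    score <- matrix(log(w) - log(-log(stats::runif(mc))), m, C)
    pick <- max.col(score, ties.method = "first")
    sel <- (pick - 1L) * m + seq_len(m)
    good <- matrix(w, m, C)[cbind(seq_len(m), pick)] > 0
    agt <- need[good]
    resx[agt] <- px[sel[good]]
    resy[agt] <- py[sel[good]]
    resh[agt] <- hh[sel[good]]
    need <- need[!good]
    if (!length(need)) return(list(x = resx, y = resy, heading = resh))
  }
  stop("movement rejection cap exceeded (degenerate geometry?)")
}

#' Habitat-weighted movement step
#'
#' Draws `n_candidates` CRW proposals per agent and selects the next
#' location with probability proportional to the habitat weight at each
#' candidate endpoint (candidates outside the domain get weight zero; if
#' every candidate has weight zero the whole set is redrawn).
#'
#' @param agents agent data frame (`x`, `y`, `heading`, and `tx`, `ty`,
#'   `territorial` when `spec$territorial`)
#' @param spec a [scenario_spec()] with `habitat_selection = TRUE`
#' @param domain a `study_domain`
#' @param raster a `habitat_raster`
#' @param weights named habitat weights by class label (reference weight
#'   must be positive)
#' @param cfg a [movement_config()]
#' @return list with accepted `x`, `y`, `heading`
#' @export
habitat_weighted_step <- function(agents, spec, domain, raster, weights,
                                  cfg = movement_config()) {
  wcode <- weights_by_code(raster, weights)
  if (wcode[match(raster$reference, raster$class_labels)] <= 0) {
    stop("reference class must have positive weight")
  }
  step_agents(agents, spec, domain, raster, wcode, cfg)
}

# Habitat weights aligned to raster class codes.
weights_by_code <- function(raster, weights) {
  w <- weights[raster$class_labels]
  if (anyNA(w)) stop("habitat weights missing for class(es): ",
                     paste(raster$class_labels[is.na(w)], collapse = ", "))
  unname(w)
}

#' Initialize the agent population
#'
#' Places `initial_n` agents (or groups) in the domain: uniformly for
#' scenarios A-C, from an intensity proportional to exp(F) of a Matern
#' field for D/F, additionally multiplied by the habitat weight for E/F.
#' Grouped scenarios draw group sizes 1 + Poisson(`group_mean_extra`);
#' territorial flags are assigned to `territorial_fraction` of agents with
#' the territory centre at the initial location.
#'
#' @param spec a [scenario_spec()]
#' @param domain a `study_domain`
#' @param raster a `habitat_raster` (required for habitat-selective
#'   scenarios; any raster covering the domain otherwise)
#' @param cfg a [movement_config()]
#' @return agent data frame: `id`, `x`, `y`, `heading`, `group_size`,
#'   `territorial`, `tx`, `ty`
#' @export
init_population <- function(spec, domain, raster = NULL,
                            cfg = movement_config()) {
  n0 <- spec$initial_n
  if (!spec$hetero_init && !spec$habitat_selection) {
    pts <- enforce_boundary(domain, function(m) {
      bb <- domain$bbox
      list(x = stats::runif(m, bb["xmin"], bb["xmax"]),
           y = stats::runif(m, bb["ymin"], bb["ymax"]))
    }, n0, cfg$max_tries)
    x <- pts$x; y <- pts$y
  } else {
    if (is.null(raster)) stop("`raster` is required for scenarios D/E/F")
    cc <- raster_cell_centers(raster)
    inside <- domain_contains(domain, cc$x, cc$y)
    cc <- cc[inside, , drop = FALSE]
    wcell <- rep(1, nrow(cc))
    if (spec$habitat_selection) {
      wcell <- weights_by_code(raster, spec$habitat_weights_true)[cc$class]
    }
    if (spec$hetero_init && spec$init_field_variance > 0) {
      fld <- matern_field_grid(domain, spec$init_field_scale,
                               spec$init_field_variance)
      f <- fld$interp(cc$x, cc$y)
      wcell <- wcell * exp(f - max(f))
    }
    idx <- sample.int(nrow(cc), n0, replace = TRUE, prob = wcell)
    cs <- raster$cell_size
    x <- cc$x[idx] + stats::runif(n0, -cs / 2, cs / 2)
    y <- cc$y[idx] + stats::runif(n0, -cs / 2, cs / 2)
    # jittered points in boundary cells may leave the domain: snap to centre
    out <- !domain_contains(domain, x, y)
    x[out] <- cc$x[idx[out]]
    y[out] <- cc$y[idx[out]]
  }
  gs <- if (spec$grouped) 1L + stats::rpois(n0, cfg$group_mean_extra) else rep(1L, n0)
  agents <- data.frame(id = seq_len(n0), x = x, y = y,
                       heading = stats::runif(n0, 0, 2 * pi),
                       group_size = gs, territorial = FALSE, tx = x, ty = y)
  assign_territorial(agents, spec, cfg)
}

#' Yearly territorial assignment
#'
#' Re-draws which agents are territorial (a fresh
#' `territorial_fraction` sample each year) and sets every territory centre
#' to the agent's current location, i.e. its original location that year.
#'
#' @inheritParams init_population
#' @param agents agent data frame
#' @export
assign_territorial <- function(agents, spec, cfg = movement_config()) {
  n <- nrow(agents)
  agents$territorial <- if (spec$territorial) {
    stats::runif(n) < cfg$territorial_fraction
  } else rep(FALSE, n)
  agents$tx <- agents$x
  agents$ty <- agents$y
  agents
}

#' Yearly growth-rate draw
#'
#' @param cfg a [demography_config()]
#' @param n number of draws (one per year)
#' @return log-normal growth-rate expectation(s) \eqn{\mu}
#' @export
sample_growth_rate <- function(cfg = demography_config(), n = 1) {
  stats::rlnorm(n, cfg$env_log_mean, cfg$env_log_sd)
}

#' Birth-death update
#'
#' Each agent is replaced by a Poisson(\eqn{\mu}) number of successors at
#' its current location: 0 = death, 1 = survival, k >= 2 = survival plus
#' k - 1 new agents.  In grouped scenarios the whole group dies, survives or
#' produces new groups whose sizes are drawn afresh from
#' 1 + Poisson(`group_mean_extra`).
#'
#' @param agents agent data frame
#' @param mu expected number of successors per agent, >= 0
#' @param spec a [scenario_spec()]
#' @param cfg a [movement_config()]
#' @return updated agent data frame (ids renumbered)
#' @export
birth_death_update <- function(agents, mu, spec, cfg = movement_config()) {
  if (mu < 0) stop("`mu` must be >= 0")
  n <- nrow(agents)
  k <- stats::rpois(n, mu)
  surv <- agents[k >= 1L, , drop = FALSE]
  parents <- rep(seq_len(n), pmax(k - 1L, 0L))
  born <- agents[parents, , drop = FALSE]
  if (nrow(born)) {
    born$group_size <- if (spec$grouped) {
      1L + stats::rpois(nrow(born), cfg$group_mean_extra)
    } else rep(1L, nrow(born))
    born$heading <- stats::runif(nrow(born), 0, 2 * pi)
  }
  out <- rbind(surv, born)
  if (nrow(out)) {
    out$id <- seq_len(nrow(out))
    out$tx <- out$x
    out$ty <- out$y
  }
  rownames(out) <- NULL
  out
}

#' Simulate one survey season of movement
#'
#' Steps every agent `days * 24 / step_hours` times under the scenario's
#' step law with boundary rejection, recording all fixes.
#'
#' @param agents agent data frame (see [init_population()])
#' @param spec a [scenario_spec()]
#' @param domain a `study_domain`
#' @param raster a `habitat_raster` (required for habitat scenarios)
#' @param cfg a [movement_config()]
#' @param days season length in days (default 60)
#' @return object of class `trajectories`: fix matrices `x`, `y` of
#'   dimension (steps + 1) x n_agents, `t_days`, `id`, `group_size`,
#'   `heading_final`
#' @export
simulate_season <- function(agents, spec, domain, raster = NULL,
                            cfg = movement_config(), days = 60) {
  steps <- round(days * 24 / cfg$step_hours)
  n <- nrow(agents)
  X <- matrix(NA_real_, steps + 1L, n)
  Y <- matrix(NA_real_, steps + 1L, n)
  X[1L, ] <- agents$x
  Y[1L, ] <- agents$y
  wcode <- if (spec$habitat_selection) {
    if (is.null(raster)) stop("`raster` is required for habitat scenarios")
    weights_by_code(raster, spec$habitat_weights_true)
  } else NULL
  cur <- agents
  for (s in seq_len(steps)) {
    st <- step_agents(cur, spec, domain, raster, wcode, cfg)
    cur$x <- st$x
    cur$y <- st$y
    cur$heading <- st$heading
    X[s + 1L, ] <- st$x
    Y[s + 1L, ] <- st$y
  }
  structure(list(x = X, y = Y,
                 t_days = (0:steps) * cfg$step_hours / 24,
                 id = agents$id, group_size = agents$group_size,
                 heading_final = cur$heading),
            class = "trajectories")
}

#' @export
print.trajectories <- function(x, ...) {
  cat(sprintf("Trajectories: %d agents, %d fixes each (%.1f days at %g h)\n",
              ncol(x$x), nrow(x$x), max(x$t_days),
              diff(x$t_days[1:2]) * 24))
  invisible(x)
}

#' End-of-season agent state
#'
#' Carries agents forward to the next year: locations and headings are the
#' last fix of the season's trajectories.
#'
#' @param agents agent data frame used to simulate the season
#' @param traj the matching `trajectories` object
#' @export
season_end_state <- function(agents, traj) {
  last <- nrow(traj$x)
  agents$x <- traj$x[last, ]
  agents$y <- traj$y[last, ]
  agents$heading <- traj$heading_final
  agents
}

#' Export trajectories as a data frame
#'
#' @param x a `trajectories` object
#' @param ... unused
#' @return data frame with `agent_id`, `group_size`, `t_days`, `x_km`, `y_km`
#' @export
as.data.frame.trajectories <- function(x, ...) {
  nfix <- nrow(x$x)
  n <- ncol(x$x)
  data.frame(agent_id = rep(x$id, each = nfix),
             group_size = rep(x$group_size, each = nfix),
             t_days = rep(x$t_days, times = n),
             x_km = as.vector(x$x), y_km = as.vector(x$y))
}
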
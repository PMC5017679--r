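#' Experiment configuration
#'
#' Settings of one simulation experiment: the scenario, survey design and
#' estimation methods.  The full design is T = 20 years, a network of 1610
#' triangles of which 500 are surveyed per year, 10 collars per year and an
#' initial population of 200 individuals (40 groups).  `scale` shrinks the
#' domain area, network, surveyed sample and population together, keeping
#' density and per-transect encounter rates at the full-design values so
#' that scaled runs exercise the same statistical regime.
#'
#' @param scenario scenario code "A".."F"
#' @param years number of survey years
#' @param scale joint scale factor in (0, 1]
#' @param replicates replicate data sets
#' @param seed base seed; replicate r uses `seed + r - 1`
#' @param methods estimators to run, subset of "FMP", "T1", "T2", "ST"
#' @param n_network,n_surveyed,initial_n design sizes; `NULL` = scaled
#'   defaults
#' @param n_collars GPS collars per year
#' @param estimate_weights estimate habitat weights from the simulated GPS
#'   data? (`NULL` = only for scenarios E and F, where habitat matters)
#' @param season_days counting-season length (days)
#' @param landscape_cell_km,clustering_scale,proportions synthetic
#'   landscape settings for habitat scenarios
#' @param effort_spacing perimeter sampling interval (km)
#' @param n_boot FMP bootstrap resamples
#' @param mcmc_iter,mcmc_warmup,mcmc_thin MCMC schedule for T1/T2/ST
#' @param st_cell_km integration grid resolution for the ST totals (km)
#' @return list of class `experiment_config`
#' @export
experiment_config <- function(scenario = "A", years = 20, scale = 1,
                              replicates = 1, seed = 1,
                              methods = c("FMP", "T1", "T2"),
                              n_network = NULL, n_surveyed = NULL,
                              initial_n = NULL, n_collars = 10,
                              estimate_weights = NULL, season_days = 60,
                              landscape_cell_km = 0.25,
                              clustering_scale = 25,
                              proportions = c(artificial = 0.05,
                                              agricultural = 0.10,
                                              forest = 0.60,
                                              wetland = 0.20,
                                              water = 0.05),
                              effort_spacing = 0.025, n_boot = 1000,
                              mcmc_iter = 8000, mcmc_warmup = 3000,
                              mcmc_thin = 5, st_cell_km = 25) {
  stopifnot(scale > 0, scale <= 1, replicates >= 1, years >= 1)
  grouped <- scenario %in% c("C", "F")
  habitat <- scenario %in% c("E", "F")
  structure(list(
    scenario = scenario, years = as.integer(years), scale = scale,
    replicates = as.integer(replicates), seed = as.integer(seed),
    methods = methods,
    n_network = as.integer(n_network %||% max(2, round(1610 * scale))),
    n_surveyed = as.integer(n_surveyed %||% max(2, round(500 * scale))),
    initial_n = as.integer(initial_n %||%
                             max(2, round((if (grouped) 40 else 200) * scale))),
    n_collars = as.integer(n_collars),
    estimate_weights = estimate_weights %||% habitat,
    season_days = as.integer(season_days),
    landscape_cell_km = landscape_cell_km,
    clustering_scale = clustering_scale, proportions = proportions,
    effort_spacing = effort_spacing, n_boot = as.integer(n_boot),
    mcmc_iter = as.integer(mcmc_iter),
    mcmc_warmup = as.integer(mcmc_warmup),
    mcmc_thin = as.integer(mcmc_thin), st_cell_km = st_cell_km
  ), class = "experiment_config")
}

#' Write / read an experiment configuration (YAML)
#'
#' @param config an `experiment_config`
#' @param file path
#' @export
write_experiment_config <- function(config, file) {
  v <- unclass(config)
  v$proportions <- as.list(v$proportions)  # keep class names in the YAML map
  yaml::write_yaml(v, file)
  invisible(file)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(file) {
  v <- yaml::read_yaml(file)
  v$proportions <- unlist(v$proportions)
  v$methods <- unlist(v$methods)
  do.call(experiment_config, v)
}

#' Run one replicate of the simulation study
#'
#' Generates the landscape, transect network and agent population, runs the
#' yearly cycle (birth-death update, territorial re-assignment, 60-day
#' season, survey, collaring), then fits the requested estimators and
#' collects per-year truth and estimates.  Deterministic given
#' `(config$seed, replicate)`.
#'
#' @param config an [experiment_config()]
#' @param replicate replicate index (1-based)
#' @return list with `truth` (year, N_true), `counts` (survey records),
#'   `bursts` (GPS), `EL_hat`, `weights` (used for effort and area),
#'   `weights_boot` (bootstrap intervals when weights were estimated),
#'   `snapshots` (mid-season locations per year), `fits`, and `result`
#'   (per method x year: estimate, intervals, failure flag)
#' @export
run_replicate <- function(config, replicate = 1L) {
  set.seed(as.integer((config$seed + replicate - 1) %% .Machine$integer.max))
  side <- sqrt(config$scale)
  domain <- study_domain(width = 400 * side, height = 830.44 * side)
  spec <- scenario_spec(config$scenario, initial_n = config$initial_n)
  habitat <- spec$habitat_selection
  raster <- if (habitat) {
    synthetic_landscape(domain, config$landscape_cell_km,
                        config$proportions, config$clustering_scale)
  } else {
    uniform_raster(domain, cell_size = 10)
  }
  cfg <- movement_config()
  demog <- demography_config()
  network <- generate_transect_network(
    config$n_network, domain, raster,
    min_reference_fraction = if (habitat) 0.9 else 0,
    spacing = max(config$effort_spacing, raster$cell_size / 4),
    max_tries = 1000L * config$n_network)

  agents <- init_population(spec, domain, raster, cfg)
  counts <- NULL
  bursts <- list()
  truth <- data.frame(year = seq_len(config$years), N_true = NA_real_)
  snapshots <- vector("list", config$years)
  mid_fix <- round(config$season_days / 2) * round(24 / cfg$step_hours) + 1L

  for (t in seq_len(config$years)) {
    if (t > 1L) {
      mu <- sample_growth_rate(demog)
      agents <- birth_death_update(agents, mu, spec, cfg)
      if (!nrow(agents)) {  # extinct: remaining years have N = 0
        truth$N_true[t:config$years] <- 0
        break
      }
    }
    agents <- assign_territorial(agents, spec, cfg)
    truth$N_true[t] <- sum(agents$group_size)
    traj <- simulate_season(agents, spec, domain, raster, cfg,
                            days = config$season_days)
    snapshots[[t]] <- data.frame(x = traj$x[mid_fix, ],
                                 y = traj$y[mid_fix, ],
                                 w = traj$group_size)
    counts <- rbind(counts,
                    survey_year(traj, network, config$n_surveyed, raster,
                                domain, year = t,
                                spacing = max(config$effort_spacing,
                                              raster$cell_size / 4)))
    ids <- collar_individuals(agents, config$n_collars)
    bursts <- c(bursts, trajectories_to_bursts(traj, ids, year = t))
    agents <- season_end_state(agents, traj)
  }

  EL_hat <- estimate_daily_distance(bursts)
  weights_boot <- NULL
  if (habitat && config$estimate_weights) {
    hw <- habitat_weights(bursts, raster, domain)
    weights <- hw$h
    weights[is.na(weights)] <- 0  # classes never available: no density
    weights_boot <- bootstrap_habitat_weights(hw$usages, raster$reference)
  } else if (habitat) {
    weights <- spec$habitat_weights_true[raster$class_labels]
  } else {
    weights <- stats::setNames(rep(1, length(raster$class_labels)),
                               raster$class_labels)
  }
  counts <- apply_effort_weights(counts, weights)
  area_w <- habitat_weighted_area(raster, weights, domain)

  fits <- list()
  result <- NULL
  years_obs <- sort(unique(counts$year))
  eff <- vapply(years_obs,
                function(t) sum(counts$M_km[counts$year == t] *
                                  counts$D_days[counts$year == t]),
                numeric(1))
  tot <- vapply(years_obs,
                function(t) sum(counts$count[counts$year == t]), numeric(1))
  off <- log(2 / pi) + log(EL_hat) + log(eff)

  if ("FMP" %in% config$methods) {
    rows <- lapply(seq_along(years_obs), function(k) {
      rec <- counts[counts$year == years_obs[k], ]
      f <- fmp_fit(rec, EL_hat, area_w, n_boot = config$n_boot)
      iv <- f$intervals %||% matrix(NA_real_, 2, 2,
                                    dimnames = list(c("lo", "hi"),
                                                    c("50%", "95%")))
      data.frame(method = "FMP", year = years_obs[k], N_hat = f$total,
                 lo50 = iv["lo", "50%"], hi50 = iv["hi", "50%"],
                 lo95 = iv["lo", "95%"], hi95 = iv["hi", "95%"],
                 failed = classify_failure(f$total))
    })
    result <- rbind(result, do.call(rbind, rows))
  }
  for (m in intersect(c("T1", "T2"), config$methods)) {
    prior <- prior_preset(if (m == "T1") "default" else "relaxed")
    fit <- fit_temporal(tot, off, prior, n_iter = config$mcmc_iter,
                        n_warmup = config$mcmc_warmup,
                        thin = config$mcmc_thin)
    fits[[m]] <- fit
    result <- rbind(result,
                    totals_to_rows(fit, m, years_obs, area_w))
  }
  if ("ST" %in% config$methods) {
    sites <- unique(counts[c("transect_id", "x", "y")])
    names(sites)[1] <- "site_id"
    stc <- counts
    stc$site_id <- stc$transect_id
    stc$offset_log <- log(2 / pi) + log(EL_hat) +
      log(stc$M_km * stc$D_days)
    fit <- fit_spatiotemporal(stc, sites,
                              prior = prior_preset("relaxed"),
                              n_iter = config$mcmc_iter,
                              n_warmup = config$mcmc_warmup,
                              thin = config$mcmc_thin)
    fits[["ST"]] <- fit
    rows <- lapply(years_obs, function(t) {
      if (!isTRUE(fit$converged)) {
        return(data.frame(method = "ST", year = t, N_hat = NA_real_,
                          lo50 = NA_real_, hi50 = NA_real_,
                          lo95 = NA_real_, hi95 = NA_real_, failed = TRUE))
      }
      pe <- population_estimate(fit, domain, raster, weights, year = t,
                                cell_km = config$st_cell_km,
                                n_draws_max = 150)
      data.frame(method = "ST", year = t, N_hat = pe$median,
                 lo50 = pe$intervals["lo", "50%"],
                 hi50 = pe$intervals["hi", "50%"],
                 lo95 = pe$intervals["lo", "95%"],
                 hi95 = pe$intervals["hi", "95%"],
                 failed = classify_failure(pe$median))
    })
    result <- rbind(result, do.call(rbind, rows))
  }
  result <- merge(result, truth, by = "year")
  result$replicate <- replicate
  rownames(result) <- NULL
  list(truth = truth, counts = counts, bursts = bursts, EL_hat = EL_hat,
       weights = weights, weights_boot = weights_boot, area_w = area_w,
       snapshots = snapshots, fits = fits, domain = domain,
       raster = raster, result = result)
}

totals_to_rows <- function(fit, method, years_obs, area_w) {
  if (!isTRUE(fit$converged)) {
    return(data.frame(method = method, year = years_obs, N_hat = NA_real_,
                      lo50 = NA_real_, hi50 = NA_real_, lo95 = NA_real_,
                      hi95 = NA_real_, failed = TRUE))
  }
  Nd <- posterior_total(fit, area_w)
  do.call(rbind, lapply(seq_along(years_obs), function(k) {
    q <- stats::quantile(Nd[, k], c(0.5, 0.25, 0.75, 0.025, 0.975),
                         names = FALSE)
    data.frame(method = method, year = years_obs[k], N_hat = q[1],
               lo50 = q[2], hi50 = q[3], lo95 = q[4], hi95 = q[5],
               failed = classify_failure(q[1]))
  }))
}

#' Run a full experiment
#'
#' Runs all replicates of the configuration and aggregates the evaluation
#' metrics per method: mean and standard error of the log accuracy ratio
#' alpha (failed estimates excluded), its 95 % quantiles, the pooled
#' regression slope beta and R^2 of log-estimated on log-true totals
#' (pooled over years and replicates), interval coverage at 50 % and 95 %,
#' and the failed fraction.
#'
#' @param config an [experiment_config()]
#' @param keep_replicates keep the full per-replicate outputs? (memory)
#' @return list of class `evaluation_report`: `report` (one row per
#'   method), `results` (per replicate x method x year), and optionally
#'   `replicates`
#' @export
run_experiment <- function(config, keep_replicates = FALSE) {
  reps <- lapply(seq_len(config$replicates),
                 function(r) run_replicate(config, r))
  results <- do.call(rbind, lapply(reps, `[[`, "result"))
  report <- evaluate_results(results)
  report$scenario <- config$scenario
  structure(list(report = report, results = results,
                 replicates = if (keep_replicates) reps),
            class = "evaluation_report")
}

#' Aggregate evaluation metrics from per-year results
#'
#' @param results data frame with `method`, `year`, `replicate`, `N_hat`,
#'   `N_true`, interval columns and `failed`
#' @return one-row-per-method data frame of metrics
#' @export
evaluate_results <- function(results) {
  do.call(rbind, lapply(split(results, results$method), function(d) {
    ok <- d[!d$failed & is.finite(d$N_hat), , drop = FALSE]
    al <- alpha_log_ratio(ok$N_hat, ok$N_true)
    reg <- if (nrow(ok) >= 3 && stats::var(log(ok$N_true + 1)) > 0) {
      regression_metrics(ok$N_hat, ok$N_true)
    } else list(beta = NA_real_, r_squared = NA_real_)
    data.frame(method = d$method[1],
               mean_alpha = mean(al),
               se_alpha = stats::sd(al) / sqrt(length(al)),
               alpha_lo = unname(stats::quantile(al, 0.025)),
               alpha_hi = unname(stats::quantile(al, 0.975)),
               beta = reg$beta, r_squared = reg$r_squared,
               coverage50 = interval_coverage(ok$N_true, ok$lo50, ok$hi50),
               coverage95 = interval_coverage(ok$N_true, ok$lo95, ok$hi95),
               failed_fraction = mean(d$failed),
               n = nrow(ok))
  }))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report",
      if (!is.null(x$report$scenario)) paste0("(Scenario ",
                                              x$report$scenario[1], ")"),
      "\n")
  print(format(x$report[c("method", "mean_alpha", "se_alpha", "beta",
                          "r_squared", "coverage50", "coverage95",
                          "failed_fraction")],
               digits = 3), row.names = FALSE)
  invisible(x)
}
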
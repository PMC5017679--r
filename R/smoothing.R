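#' Negative binomial log-pmf (mean parameterization)
#'
#' Log probability of a count under NB with mean `mu` and overdispersion
#' `r` (variance `mu + mu^2 / r`); the success probability of the classical
#' parameterization is `r / (r + mu)`.  As `r` grows the distribution
#' approaches Poisson(`mu`).
#'
#' @param x nonnegative integer count(s)
#' @param mu mean, > 0
#' @param r overdispersion (size), > 0
#' @return log pmf value(s)
#' @export
nb_logpmf <- function(x, mu, r) {
  if (any(mu <= 0) || any(r <= 0)) stop("`mu` and `r` must be > 0")
  if (any(x < 0) || any(x != round(x))) stop("`x` must be nonnegative integers")
  stats::dnbinom(x, size = r, mu = mu, log = TRUE)
}

#' Hyperprior presets
#'
#' Two presets for the state-space smoothing models, specified on the
#' transformed latent hyperparameters \eqn{\theta_1 = \log\tau} (log
#' precision of the innovations / field, \eqn{\tau = 1/\sigma^2}) and
#' \eqn{\theta_2 = \log((1+\phi)/(1-\phi))}: \describe{
#'   \item{default}{diffuse Gamma(1, 5e-5) prior on the precision and a
#'     broad Gaussian (precision 0.15) on \eqn{\theta_2}; this emulates the
#'     heavy-shrinkage regime in which the temporal model over-smooths
#'     (model "T1").}
#'   \item{relaxed}{Gaussian(0, precision 1) on \eqn{\theta_1} and
#'     Gaussian(1, precision 1) on \eqn{\theta_2}; a less smoothing prior
#'     (model "T2").}
#' }
#' Both presets use b ~ N(0, 10^2), log r ~ N(0, 1.5^2) and, for the
#' spatio-temporal model, log kappa ~ N(log 0.01, 1.5^2) (inverse range
#' centred on 100 km).
#'
#' @param name "default" or "relaxed"
#' @param b_mean,b_sd intercept prior
#' @param r_meanlog,r_sdlog log-normal prior on the overdispersion
#' @param kappa_meanlog,kappa_sdlog log-normal prior on the inverse range
#' @return list of class `prior_preset`
#' @export
prior_preset <- function(name = c("relaxed", "default"),
                         b_mean = 0, b_sd = 10,
                         r_meanlog = 0, r_sdlog = 1.5,
                         kappa_meanlog = log(0.01), kappa_sdlog = 1.5) {
  name <- match.arg(name)
  if (name == "relaxed") {
    theta1 <- list(type = "normal", mean = 0, sd = 1)
    theta2 <- list(mean = 1, sd = 1)
  } else {
    theta1 <- list(type = "loggamma", shape = 1, rate = 5e-5)
    theta2 <- list(mean = 0, sd = sqrt(1 / 0.15))
  }
  structure(list(name = name, theta1 = theta1, theta2 = theta2,
                 b_mean = b_mean, b_sd = b_sd,
                 r_meanlog = r_meanlog, r_sdlog = r_sdlog,
                 kappa_meanlog = kappa_meanlog, kappa_sdlog = kappa_sdlog),
            class = "prior_preset")
}

# theta vector layout: (b, theta1, theta2, log r[, log kappa])
theta_to_pars <- function(theta, spatial) {
  list(b = theta[1], sigma2 = exp(-theta[2]), phi = tanh(theta[3] / 2),
       r = exp(theta[4]),
       kappa = if (spatial) exp(theta[5]) else NA_real_)
}

log_prior_theta <- function(theta, prior, spatial) {
  lp <- stats::dnorm(theta[1], prior$b_mean, prior$b_sd, log = TRUE) +
    stats::dnorm(theta[3], prior$theta2$mean, prior$theta2$sd, log = TRUE) +
    stats::dnorm(theta[4], prior$r_meanlog, prior$r_sdlog, log = TRUE)
  lp <- lp + if (prior$theta1$type == "normal") {
    stats::dnorm(theta[2], prior$theta1$mean, prior$theta1$sd, log = TRUE)
  } else {  # Gamma prior on the precision tau = exp(theta1), with Jacobian
    stats::dgamma(exp(theta[2]), prior$theta1$shape, prior$theta1$rate,
                  log = TRUE) + theta[2]
  }
  if (spatial) {
    lp <- lp + stats::dnorm(theta[5], prior$kappa_meanlog, prior$kappa_sdlog,
                            log = TRUE)
  }
  lp
}

#' Simulate the latent state process
#'
#' Draws from the prior of the AR1 (temporal) or separable AR1-in-time x
#' Matern-in-space (spatio-temporal) latent field, with stationary
#' initialization \eqn{z_1 \sim N(0, \sigma^2/(1-\phi^2))} (marginals
#' matched across time).
#'
#' @param T_years number of years
#' @param phi AR1 coefficient, |phi| < 1
#' @param sigma2 innovation variance
#' @param coords optional site coordinate matrix (S x 2); when given, the
#'   innovations are spatially correlated with Matern(`kappa`, `nu`)
#' @param kappa inverse spatial range (1/km)
#' @param nu Matern smoothness
#' @param n number of independent draws
#' @return temporal: `n` x `T_years` matrix; spatio-temporal: array
#'   `n` x S x `T_years`
#' @export
simulate_latent <- function(T_years, phi, sigma2, coords = NULL,
                            kappa = NULL, nu = 1, n = 1) {
  stopifnot(abs(phi) < 1, sigma2 >= 0, T_years >= 1)
  sig <- sqrt(sigma2)
  if (is.null(coords)) {
    out <- matrix(0, n, T_years)
    out[, 1] <- stats::rnorm(n, 0, sig / sqrt(1 - phi^2))
    for (t in seq_len(T_years)[-1]) {
      out[, t] <- phi * out[, t - 1] + sig * stats::rnorm(n)
    }
    return(out)
  }
  S <- nrow(coords)
  R <- matern_covariance(as.matrix(stats::dist(coords)), 1, kappa, nu)
  diag(R) <- 1 + 1e-8
  Lt <- t(chol(R))
  out <- array(0, c(n, S, T_years))
  for (i in seq_len(n)) {
    z <- (sig / sqrt(1 - phi^2)) * drop(Lt %*% stats::rnorm(S))
    out[i, , 1] <- z
    for (t in seq_len(T_years)[-1]) {
      z <- phi * z + sig * drop(Lt %*% stats::rnorm(S))
      out[i, , t] <- z
    }
  }
  out
}

# --- MCMC engine -----------------------------------------------------------
#
# Joint posterior over hyperparameters theta and latent field z, sampled by
# alternating (i) elliptical slice sampling of the whitened innovations u
# (non-centred parameterization), (ii) adaptive random-walk Metropolis on
# theta with u held fixed, and (iii) an interweaved Metropolis move on the
# variance/correlation hyperparameters with the *field* z held fixed
# (centred parameterization), which restores mixing when the data are
# informative about z.

mcmc_nb_ar1 <- function(x, offset_log, site_idx, year_idx, S, T_years,
                        dmat = NULL, prior = prior_preset("relaxed"),
                        nu = 1, n_iter = 8000, n_warmup = 3000, thin = 5,
                        jitter = 1e-8) {
  spatial <- !is.null(dmat) && S > 1L
  d <- if (spatial) 5L else 4L
  obs <- cbind(site_idx, year_idx)

  kappa_cache <- NA_real_
  Lt_cache <- NULL
  get_Lt <- function(kappa) {
    if (!spatial) return(NULL)
    if (!isTRUE(kappa == kappa_cache)) {
      R <- matern_covariance(dmat, 1, kappa, nu)
      diag(R) <- 1 + jitter
      Lt_cache <<- t(chol(R))
      kappa_cache <<- kappa
    }
    Lt_cache
  }

  build_z <- function(U, pars) {
    sig <- sqrt(pars$sigma2)
    phi <- pars$phi
    if (!spatial) {  # scalar AR1 recursion
      u <- as.vector(U)
      z <- numeric(T_years)
      z[1] <- sig / sqrt(1 - phi^2) * u[1]
      for (t in seq_len(T_years)[-1]) z[t] <- phi * z[t - 1] + sig * u[t]
      return(matrix(z, 1))
    }
    LU <- get_Lt(pars$kappa) %*% U
    Z <- matrix(0, S, T_years)
    Z[, 1] <- (sig / sqrt(1 - phi^2)) * LU[, 1]
    for (t in seq_len(T_years)[-1]) {
      Z[, t] <- phi * Z[, t - 1] + sig * LU[, t]
    }
    Z
  }

  obs_loglik <- function(Z, pars) {
    mu <- exp(offset_log + pars$b + Z[obs])
    ll <- sum(stats::dnbinom(x, size = pars$r, mu = mu, log = TRUE))
    if (is.finite(ll)) ll else -Inf
  }

  # log N(z | 0, AR1 x Matern) in the centred parameterization
  z_logprior <- function(Z, pars) {
    sig <- sqrt(pars$sigma2)
    phi <- pars$phi
    if (!spatial) {
      z <- as.vector(Z)
      return(stats::dnorm(z[1], 0, sig / sqrt(1 - phi^2), log = TRUE) +
               sum(stats::dnorm(z[-1] - phi * z[-T_years], 0, sig,
                                log = TRUE)))
    }
    if (spatial) {
      Lt <- get_Lt(pars$kappa)
      ldet <- sum(log(diag(Lt)))
      q <- function(v, s) {
        w <- forwardsolve(Lt, v) / s
        -S / 2 * log(2 * pi) - S * log(s) - ldet - 0.5 * sum(w^2)
      }
    } else {
      q <- function(v, s) stats::dnorm(v, 0, s, log = TRUE)
    }
    lp <- q(Z[, 1], sig / sqrt(1 - phi^2))
    for (t in seq_len(T_years)[-1]) {
      lp <- lp + q(Z[, t] - phi * Z[, t - 1], sig)
    }
    sum(lp)
  }

  # recover whitened innovations from a field (inverse of build_z)
  u_from_z <- function(Z, pars) {
    sig <- sqrt(pars$sigma2)
    phi <- pars$phi
    if (!spatial) {
      z <- as.vector(Z)
      return(matrix(c(z[1] * sqrt(1 - phi^2),
                      z[-1] - phi * z[-T_years]) / sig, 1))
    }
    E <- Z
    E[, 1] <- Z[, 1] * sqrt(1 - phi^2)
    for (t in seq_len(T_years)[-1]) {
      E[, t] <- Z[, t] - phi * Z[, t - 1]
    }
    E <- E / sig
    forwardsolve(get_Lt(pars$kappa), E)
  }

  # initialization
  b0 <- log((sum(x) + 0.5) / sum(exp(offset_log)))
  theta <- c(b0, log(1 / 0.25), log(3), 0, if (spatial) log(0.02))
  U <- matrix(0, S, T_years)
  pars <- theta_to_pars(theta, spatial)
  Zcur <- build_z(U, pars)
  ll <- obs_loglik(Zcur, pars)
  lp <- log_prior_theta(theta, prior, spatial)

  n_keep <- floor((n_iter - n_warmup) / thin)
  th_draws <- matrix(NA_real_, n_keep, d)
  z_draws <- array(NA_real_, c(n_keep, S, T_years))
  kept <- 0L

  # adaptive RWM state (separate scales per move type)
  lam <- 0.3
  lam_r <- 0.6
  lam_c <- 0.25
  prop_chol <- diag(0.2, d)
  hist_th <- matrix(NA_real_, n_warmup, d)
  acc_nc <- acc_c <- try_nc <- try_c <- 0L

  for (it in seq_len(n_iter)) {
    ## (i) elliptical slice sample u
    for (rep in 1:2) {
      nu_e <- matrix(stats::rnorm(S * T_years), S, T_years)
      logy <- ll + log(stats::runif(1))
      ang <- stats::runif(1, 0, 2 * pi)
      lo <- ang - 2 * pi
      hi <- ang
      repeat {
        Up <- U * cos(ang) + nu_e * sin(ang)
        Zp <- build_z(Up, pars)
        llp <- obs_loglik(Zp, pars)
        if (llp > logy) {
          U <- Up
          Zcur <- Zp
          ll <- llp
          break
        }
        if (ang < 0) lo <- ang else hi <- ang
        if (hi - lo < 1e-10) break
        ang <- stats::runif(1, lo, hi)
      }
    }

    ## (ii) non-centred RWM on theta
    try_nc <- try_nc + 1L
    acc_i <- 0L
    thp <- theta + lam * drop(prop_chol %*% stats::rnorm(d))
    parsp <- theta_to_pars(thp, spatial)
    lpp <- log_prior_theta(thp, prior, spatial)
    if (is.finite(lpp)) {
      Zp <- build_z(U, parsp)
      llp <- obs_loglik(Zp, parsp)
      if (log(stats::runif(1)) < llp + lpp - ll - lp) {
        theta <- thp; pars <- parsp; ll <- llp; lp <- lpp; Zcur <- Zp
        acc_nc <- acc_nc + 1L
        acc_i <- 1L
      } else if (spatial) get_Lt(pars$kappa)  # restore cache
    }

    ## (ii-b) single-coordinate move on log r (heavy-tailed marginal)
    acc_r <- 0L
    thp <- theta
    thp[4] <- theta[4] + stats::rnorm(1, 0, lam_r)
    parsp <- theta_to_pars(thp, spatial)
    lpp <- log_prior_theta(thp, prior, spatial)
    llp <- obs_loglik(Zcur, parsp)  # r does not enter the field
    if (is.finite(lpp) && log(stats::runif(1)) < llp + lpp - ll - lp) {
      theta <- thp; pars <- parsp; ll <- llp; lp <- lpp
      acc_r <- 1L
    }

    ## (iii) centred move on (theta1, theta2[, log kappa]), field fixed
    try_c <- try_c + 1L
    Z <- Zcur
    idx <- if (spatial) c(2L, 3L, 5L) else c(2L, 3L)
    acc_ci <- 0L
    thp <- theta
    thp[idx] <- theta[idx] + stats::rnorm(length(idx), 0, lam_c)
    parsp <- theta_to_pars(thp, spatial)
    lpp <- log_prior_theta(thp, prior, spatial)
    lzp <- z_logprior(Z, parsp)
    lz <- z_logprior(Z, pars)
    if (is.finite(lpp) && is.finite(lzp) &&
        log(stats::runif(1)) < lzp + lpp - lz - lp) {
      theta <- thp; lp <- lpp
      pars <- parsp
      U <- u_from_z(Z, pars)
      acc_c <- acc_c + 1L
      acc_ci <- 1L
    } else if (spatial) get_Lt(pars$kappa)

    ## (iv) translation: shift b against the field, likelihood invariant
    del <- stats::rnorm(1, 0, 0.3)
    thp <- theta
    thp[1] <- theta[1] + del
    lpp <- log_prior_theta(thp, prior, spatial)
    lzp <- z_logprior(Zcur - del, pars)
    lz <- z_logprior(Zcur, pars)
    if (is.finite(lzp) && log(stats::runif(1)) < lzp + lpp - lz - lp) {
      theta <- thp
      lp <- lpp
      pars$b <- thp[1]
      Zcur <- Zcur - del
      U <- u_from_z(Zcur, pars)
    }

    ## adaptation during warmup
    if (it <= n_warmup) {
      hist_th[it, ] <- theta
      gam <- min(0.1, 5 / sqrt(it))
      lam <- exp(log(lam) + (acc_i - 0.25) * gam)
      lam_r <- exp(log(lam_r) + (acc_r - 0.44) * gam)
      lam_c <- exp(log(lam_c) + (acc_ci - 0.30) * gam)
      if (it %% 200L == 0L && it >= 400L) {
        cv <- stats::cov(hist_th[max(1, it - 1500):it, , drop = FALSE])
        cv <- cv + diag(1e-6, d)
        prop_chol <- t(chol(cv)) * 2.38 / sqrt(d)
      }
    } else if ((it - n_warmup) %% thin == 0L && kept < n_keep) {
      kept <- kept + 1L
      th_draws[kept, ] <- theta
      z_draws[kept, , ] <- Zcur
    }
  }

  draws <- data.frame(b = th_draws[, 1], phi = tanh(th_draws[, 3] / 2),
                      sigma2 = exp(-th_draws[, 2]), r = exp(th_draws[, 4]))
  if (spatial) draws$kappa <- exp(th_draws[, 5])
  rhat <- apply(th_draws, 2, split_rhat)
  names(rhat) <- c("b", "theta1", "theta2", "logr",
                   if (spatial) "logkappa")
  list(draws = draws, z = z_draws,
       diagnostics = list(accept_noncentred = acc_nc / try_nc,
                          accept_centred = acc_c / try_c,
                          rhat = rhat))
}

# split-half R-hat from a single chain
split_rhat <- function(v) {
  n <- floor(length(v) / 2)
  if (n < 4) return(NA_real_)
  m <- cbind(v[seq_len(n)], v[n + seq_len(n)])
  W <- mean(apply(m, 2, stats::var))
  B <- n * stats::var(colMeans(m))
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the temporal smoothing model
#'
#' Bayesian negative-binomial state-space model for yearly total counts:
#' \deqn{X_t \sim \mathrm{NB}(e_t a_t, r),\quad \log a_t = b + z_t,\quad
#'   z_t = \phi z_{t-1} + \epsilon_t,\ \epsilon_t \sim N(0, \sigma^2),}
#' with stationary AR1 initialization.  The offset is
#' \eqn{\log e_t = \log(2/\pi) + \log E[L] + \log \sum_i M_{it} D_{it}}.
#' Inference is by MCMC (see the package vignette); inference divergence
#' sets the failure flag instead of raising an error.
#'
#' @param x yearly total counts, length T >= 3
#' @param offset_log log offsets \eqn{\log e_t}, same length
#' @param prior a [prior_preset()]
#' @param n_iter,n_warmup,thin MCMC schedule
#' @return object of class `rem_fit` with `draws` (b, phi, sigma2, r),
#'   `a` (posterior draws of \eqn{a_t}, draws x T), `z`, `diagnostics`,
#'   `converged`
#' @export
fit_temporal <- function(x, offset_log, prior = prior_preset("relaxed"),
                         n_iter = 8000, n_warmup = 3000, thin = 5) {
  if (length(x) < 3L) stop("need T >= 3 years")
  if (length(offset_log) != length(x) || any(!is.finite(offset_log))) {
    stop("`offset_log` must be finite and match `x`")
  }
  T_years <- length(x)
  res <- tryCatch(
    mcmc_nb_ar1(x, offset_log, rep(1L, T_years), seq_len(T_years),
                S = 1L, T_years = T_years, dmat = NULL, prior = prior,
                n_iter = n_iter, n_warmup = n_warmup, thin = thin),
    error = function(e) e)
  new_rem_fit(res, model = "temporal", x = x, offset_log = offset_log,
              prior = prior)
}

#' Fit the spatio-temporal smoothing model
#'
#' Extends [fit_temporal()] to transect-level counts with a separable
#' latent field: \eqn{z_{it} = \phi z_{i,t-1} + \epsilon_{it}} where the
#' innovations \eqn{\epsilon_t} have a Matern covariance (variance
#' \eqn{\sigma^2}, inverse range \eqn{\kappa}, smoothness \eqn{\nu = 1})
#' across sites, evaluated exactly on the site set.
#'
#' @param counts data frame with `site_id`, `year`, `count`, `offset_log`
#' @param sites data frame with `site_id`, `x`, `y` (km)
#' @param prior a [prior_preset()]
#' @param nu Matern smoothness
#' @param n_iter,n_warmup,thin MCMC schedule
#' @return `rem_fit` with `draws` (b, phi, sigma2, r, kappa), latent field
#'   draws `z` (draws x sites x years), site coordinates, `converged`
#' @export
fit_spatiotemporal <- function(counts, sites, prior = prior_preset("relaxed"),
                               nu = 1, n_iter = 6000, n_warmup = 2500,
                               thin = 5) {
  sid <- match(counts$site_id, sites$site_id)
  if (anyNA(sid)) stop("count records reference unknown sites")
  years <- sort(unique(counts$year))
  if (nrow(sites) < 2L || length(years) < 2L) {
    stop("need >= 2 distinct sites and >= 2 years")
  }
  yid <- match(counts$year, years)
  dmat <- as.matrix(stats::dist(cbind(sites$x, sites$y)))
  res <- tryCatch(
    mcmc_nb_ar1(counts$count, counts$offset_log, sid, yid,
                S = nrow(sites), T_years = length(years), dmat = dmat,
                prior = prior, nu = nu, n_iter = n_iter,
                n_warmup = n_warmup, thin = thin),
    error = function(e) e)
  new_rem_fit(res, model = "spatiotemporal", x = counts$count,
              offset_log = counts$offset_log, prior = prior,
              sites = sites, years = years, nu = nu)
}

new_rem_fit <- function(res, model, x, offset_log, prior, sites = NULL,
                        years = NULL, nu = 1) {
  if (inherits(res, "error")) {
    return(structure(list(model = model, draws = NULL, z = NULL, a = NULL,
                          converged = FALSE, error = conditionMessage(res),
                          diagnostics = list(), prior = prior,
                          sites = sites, years = years, nu = nu),
                     class = "rem_fit"))
  }
  finite <- all(is.finite(as.matrix(res$draws))) && all(is.finite(res$z))
  rh <- res$diagnostics$rhat
  converged <- finite && all(is.na(rh) | rh < 1.2) &&
    res$diagnostics$accept_noncentred > 0.02
  a <- if (model == "temporal") {
    exp(res$draws$b + res$z[, 1, ])
  } else NULL
  structure(list(model = model, draws = res$draws, z = res$z, a = a,
                 x = x, offset_log = offset_log, prior = prior,
                 sites = sites, years = years, nu = nu,
                 diagnostics = res$diagnostics, converged = converged),
            class = "rem_fit")
}

#' @export
print.rem_fit <- function(x, ...) {
  cat(sprintf("REM %s model fit (%s prior): %s\n", x$model, x$prior$name,
              if (x$converged) "converged" else "NOT CONVERGED"))
  if (!is.null(x$draws)) {
    s <- apply(x$draws, 2, stats::quantile, c(0.5, 0.025, 0.975))
    cat("posterior medians [95% CrI]:\n")
    for (p in colnames(s)) {
      cat(sprintf("  %-7s %.4g  [%.4g, %.4g]\n", p, s[1, p], s[2, p], s[3, p]))
    }
  }
  invisible(x)
}

#' Posterior draws of the density field
#'
#' For the spatio-temporal model, conditional Gaussian-process prediction
#' of the latent field at new points for one year (per posterior draw, with
#' the draw's own hyperparameters), returning draws of the density
#' \eqn{a(s, t) = \exp(b + z(s, t))}.  Points coinciding with fitted sites
#' reproduce the site's own posterior draws.  For the temporal model the
#' spatially constant \eqn{a_t} draws are returned for every point.
#'
#' @param fit a converged `rem_fit`
#' @param points matrix or data frame of prediction coordinates (x, y km)
#' @param year year (as given to the fit) to predict
#' @param n_draws_max cap on the number of posterior draws used
#' @return matrix (draws x points) of density draws; attribute
#'   `extrapolated` flags points outside the fitted sites' bounding box
#' @export
predict_density_field <- function(fit, points, year, n_draws_max = 200) {
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  points <- as.matrix(points)[, 1:2, drop = FALSE]
  P <- nrow(points)
  nd <- nrow(fit$draws)
  keep <- if (nd > n_draws_max) {
    round(seq(1, nd, length.out = n_draws_max))
  } else seq_len(nd)
  if (fit$model == "temporal") {
    ti <- if (is.null(fit$years)) year else match(year, fit$years)
    out <- matrix(fit$a[keep, ti], length(keep), P)
    attr(out, "extrapolated") <- rep(FALSE, P)
    return(out)
  }
  ti <- match(year, fit$years)
  if (is.na(ti)) stop("`year` was not in the fitted data")
  sc <- cbind(fit$sites$x, fit$sites$y)
  S <- nrow(sc)
  dps <- sqrt(outer(points[, 1], sc[, 1], "-")^2 +
                outer(points[, 2], sc[, 2], "-")^2)
  dpp <- as.matrix(stats::dist(points))
  dss <- as.matrix(stats::dist(sc))
  snap <- apply(dps, 1, which.min)
  snapd <- dps[cbind(seq_len(P), snap)]
  is_site <- snapd < 1e-9
  out <- matrix(NA_real_, length(keep), P)
  for (g in seq_along(keep)) {
    i <- keep[g]
    kap <- fit$draws$kappa[i]
    marg <- fit$draws$sigma2[i] / (1 - fit$draws$phi[i]^2)
    R <- matern_covariance(dss, 1, kap, fit$nu)
    diag(R) <- 1 + 1e-8
    Rps <- matern_covariance(dps, 1, kap, fit$nu)
    Rps[dps == 0] <- 1
    W <- Rps %*% chol2inv(chol(R))
    zm <- drop(W %*% fit$z[i, , ti])
    Cpp <- matern_covariance(dpp, 1, kap, fit$nu)
    diag(Cpp) <- 1
    Sig <- marg * (Cpp - W %*% t(Rps))
    Sig <- (Sig + t(Sig)) / 2
    ev <- eigen(Sig, symmetric = TRUE)
    ev$values[ev$values < 0] <- 0
    zdraw <- zm + drop(ev$vectors %*% (sqrt(ev$values) * stats::rnorm(P)))
    zdraw[is_site] <- fit$z[i, snap[is_site], ti]
    out[g, ] <- exp(fit$draws$b[i] + zdraw)
  }
  bb <- c(range(sc[, 1]), range(sc[, 2]))
  attr(out, "extrapolated") <- points[, 1] < bb[1] | points[, 1] > bb[2] |
    points[, 2] < bb[3] | points[, 2] > bb[4]
  out
}

#' Posterior draws of yearly population totals (temporal model)
#'
#' Multiplies the spatially constant density draws \eqn{a_t} by the
#' habitat-weighted area of the domain.
#'
#' @param fit a converged temporal `rem_fit`
#' @param area habitat-weighted area (km^2)
#' @return matrix (draws x years) of population totals
#' @export
posterior_total <- function(fit, area) {
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  if (fit$model != "temporal") {
    stop("use predict_density_field() + integrate_population() for the ",
         "spatio-temporal model")
  }
  fit$a * area
}
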
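test_that("negative binomial log-pmf is correctly parameterized", {
  # mu = 1, r = 1 is geometric with success probability 1/2
  expect_equal(nb_logpmf(0, 1, 1), log(0.5))
  expect_equal(nb_logpmf(3, 1, 1), log(0.5^4))
  # Poisson limit as r -> infinity
  expect_lt(max(abs(nb_logpmf(0:10, 3, 1e8) - dpois(0:10, 3, log = TRUE))),
            1e-6)
  # proper distribution (brute-force normalization)
  expect_gt(sum(exp(nb_logpmf(0:2000, 5, 2))), 1 - 1e-10)
  # variance mu + mu^2 / r
  xs <- 0:4000
  p <- exp(nb_logpmf(xs, 5, 2))
  expect_equal(sum(p * xs), 5, tolerance = 1e-9)
  expect_equal(sum(p * xs^2) - 25, 5 + 25 / 2, tolerance = 1e-6)
  expect_error(nb_logpmf(0, -1, 1), "> 0")
  expect_error(nb_logpmf(1.5, 1, 1), "integers")
})

test_that("latent state simulation matches AR1 theory", {
  set.seed(40)
  # phi = 0: independent N(0, sigma2)
  z0 <- simulate_latent(6, 0, 2, n = 5e4)
  expect_lt(abs(var(z0[, 3]) - 2), 0.06)
  expect_lt(abs(cor(z0[, 2], z0[, 3])), 0.02)
  # stationary variance sigma2 / (1 - phi^2) = 4/3 at phi = 0.5
  z <- simulate_latent(10, 0.5, 1, n = 1e5)
  expect_lt(abs(var(z[, 10]) / (4 / 3) - 1), 0.03)
  expect_lt(abs(var(z[, 1]) / (4 / 3) - 1), 0.03)  # initialization matched
  # lag-1 autocorrelation = phi
  expect_lt(abs(cor(z[, 9], z[, 10]) - 0.5), 0.02)
})

test_that("prior presets encode the two smoothing regimes", {
  rel <- prior_preset("relaxed")
  expect_equal(rel$theta1, list(type = "normal", mean = 0, sd = 1))
  expect_equal(rel$theta2$mean, 1)
  def <- prior_preset("default")
  expect_equal(def$theta1$type, "loggamma")
  expect_equal(def$theta1$rate, 5e-5)
})

test_that("temporal model recovers an intercept-only truth and agrees with
          an independent NB-GLM fit", {
  skip_if_not_installed("MASS")
  set.seed(41)
  T_years <- 20
  b_true <- log(6e-4)
  off <- log(2 / pi) + log(10.6) + log(runif(T_years, 5000, 7000))
  # near-degenerate state process: sigma2 ~ 0 reduces to an NB GLM
  x <- rnbinom(T_years, size = 5, mu = exp(off + b_true))
  fit <- fit_temporal(x, off, n_iter = 6000, n_warmup = 2500)
  expect_true(fit$converged)
  glm_b <- unname(coef(MASS::glm.nb(x ~ 1 + offset(off))))
  post_b <- mean(fit$draws$b)
  post_sd <- sd(fit$draws$b)
  expect_lt(abs(post_b - b_true), 3 * post_sd)
  expect_lt(abs(post_b - glm_b), 2 * post_sd)
  # posterior density draws and totals line up
  expect_equal(dim(fit$a), c(nrow(fit$draws), T_years))
  tot <- posterior_total(fit, 332176)
  expect_equal(dim(tot), dim(fit$a))
  expect_equal(tot[1, 1], fit$a[1, 1] * 332176)
})

test_that("temporal fit input validation and failure flagging", {
  expect_error(fit_temporal(c(1, 2), c(0, 0)), "T >= 3")
  expect_error(fit_temporal(c(1, 2, 3), c(0, Inf, 0)), "finite")
  # inference errors are converted to a failed fit, not an exception
  bad <- fit_temporal(c(NA_integer_, 1L, 2L), c(0, 0, 0))
  expect_s3_class(bad, "rem_fit")
  expect_false(bad$converged)
  expect_true(classify_failure(NA_real_, converged = bad$converged))
})

test_that("spatio-temporal model recovers field hyperparameters", {
  set.seed(42)
  S <- 30; T_years <- 6
  sites <- data.frame(site_id = 1:S, x = runif(S, 0, 300),
                      y = runif(S, 0, 600))
  truth <- c(sigma2 = 1, kappa = 1 / 50, phi = 0.6, r = 2, b = -1)
  off <- log(2 / pi) + log(10.6) + log(12)
  ok <- matrix(NA, 4, 3,
               dimnames = list(NULL, c("sigma2", "kappa", "phi")))
  for (rep in 1:4) {
    z <- simulate_latent(T_years, truth["phi"], truth["sigma2"],
                         coords = cbind(sites$x, sites$y),
                         kappa = truth["kappa"])[1, , ]
    cnt <- expand.grid(site_id = 1:S, year = 1:T_years)
    cnt$offset_log <- off
    cnt$count <- rnbinom(nrow(cnt), size = truth["r"],
                         mu = exp(off + truth["b"] +
                                    z[cbind(cnt$site_id, cnt$year)]))
    fit <- fit_spatiotemporal(cnt, sites, n_iter = 4000, n_warmup = 1800,
                              thin = 4)
    med <- apply(fit$draws, 2, median)
    ok[rep, ] <- abs(log(med[colnames(ok)] / truth[colnames(ok)])) < log(2)
  }
  # posterior medians within a factor 2 of truth in most replicates
  expect_gte(mean(ok[, "sigma2"]), 0.75)
  expect_gte(mean(ok[, "kappa"]), 0.75)
})

test_that("density-field prediction interpolates the fitted sites", {
  set.seed(43)
  S <- 20; T_years <- 4
  sites <- data.frame(site_id = 1:S, x = runif(S, 0, 200),
                      y = runif(S, 0, 200))
  z <- simulate_latent(T_years, 0.5, 0.8, coords = cbind(sites$x, sites$y),
                       kappa = 1 / 50)[1, , ]
  cnt <- expand.grid(site_id = 1:S, year = 1:T_years)
  cnt$offset_log <- log(60)
  cnt$count <- rnbinom(nrow(cnt), size = 3,
                       mu = exp(cnt$offset_log - 0.5 +
                                  z[cbind(cnt$site_id, cnt$year)]))
  fit <- fit_spatiotemporal(cnt, sites, n_iter = 3000, n_warmup = 1500)
  expect_true(fit$converged)
  # prediction at the fitted sites reproduces the site draws exactly
  pr <- predict_density_field(fit, cbind(sites$x, sites$y), year = 2,
                              n_draws_max = 50)
  keep <- round(seq(1, nrow(fit$draws), length.out = 50))
  expected <- exp(fit$draws$b[keep] + fit$z[keep, , 2])
  expect_lt(max(abs(pr - expected)), 1e-8)
  expect_false(any(attr(pr, "extrapolated")))
  # far beyond the range, predictive spread reverts to the prior marginal
  far <- predict_density_field(fit, cbind(2000, 2000), year = 2,
                               n_draws_max = 150)
  expect_true(all(attr(far, "extrapolated")))
  marg <- sqrt(median(fit$draws$sigma2 / (1 - fit$draws$phi^2)))
  near_sd <- sd(log(pr[, 1]))
  expect_gt(sd(log(far)), near_sd)       # screening: more uncertain far out
  expect_gt(sd(log(far)), 0.75 * marg)   # at least the latent prior spread
  # temporal fits predict a spatially constant density
  offT <- rep(log(6000), 6)
  xT <- rnbinom(6, size = 5, mu = exp(offT - 7))
  fitT <- fit_temporal(xT, offT, n_iter = 3000, n_warmup = 1500)
  prT <- predict_density_field(fitT, cbind(c(0, 10), c(0, 10)), year = 3)
  expect_equal(prT[, 1], prT[, 2])
})

test_that("the sampler matches an independent MCMC engine on the same model", {
  skip_if_not_installed("rjags")
  set.seed(205)
  off <- rep(log(2 / pi) + log(10.6) + log(6000), 20)
  z <- drop(simulate_latent(20, 0.7, 0.25))
  x <- rnbinom(20, size = 2, mu = exp(off + log(6e-4) + z))
  fit <- fit_temporal(x, off)
  expect_true(fit$converged)

  model <- "
  model {
    for (t in 1:T) {
      x[t] ~ dnegbin(p[t], r)
      p[t] <- r / (r + mu[t])
      mu[t] <- exp(off[t] + b + z[t])
    }
    z[1] ~ dnorm(0, (1 - phi^2) * tau)
    for (t in 2:T) { z[t] ~ dnorm(phi * z[t-1], tau) }
    theta1 ~ dnorm(0, 1)           # relaxed preset
    tau <- exp(theta1)
    sigma2 <- 1 / tau
    theta2 ~ dnorm(1, 1)
    phi <- (exp(theta2) - 1) / (exp(theta2) + 1)
    b ~ dnorm(0, 0.01)
    logr ~ dnorm(0, 1 / (1.5^2))
    r <- exp(logr)
  }"
  jm <- rjags::jags.model(textConnection(model),
                          data = list(x = x, off = off, T = 20),
                          n.chains = 2, quiet = TRUE)
  update(jm, 3000, progress.bar = "none")
  s <- rjags::coda.samples(jm, c("b", "phi", "sigma2"), n.iter = 15000,
                           thin = 10, progress.bar = "none")
  m <- as.matrix(s)
  for (p in c("b", "phi", "sigma2")) {
    qa <- quantile(fit$draws[[p]], c(0.25, 0.5, 0.75))
    qb <- quantile(m[, p], c(0.25, 0.5, 0.75))
    sc <- sd(m[, p])
    expect_lt(max(abs(qa - qb)) / sc, 0.25)
  }
})
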
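test_that("split_rhat matches an independently coded textbook formula", {
  set.seed(1)
  m <- matrix(rnorm(40, sd = 2), ncol = 4)
  # reference implementation written out longhand in the test
  ref <- local({
    n <- nrow(m)
    half <- floor(n / 2)
    parts <- cbind(m[1:half, ], m[(n - half + 1):n, ])
    W <- mean(apply(parts, 2, var))
    B <- half * var(colMeans(parts))
    sqrt(((half - 1) / half * W + B / half) / W)
  })
  expect_equal(split_rhat(m), ref, tolerance = 1e-12)
})

test_that("split_rhat separates mixed from unmixed chains", {
  set.seed(2)
  mixed <- matrix(rnorm(4000), ncol = 4)
  # at printed precision the converged value is 1.00-1.01 (the raw statistic
  # may dip a hair below 1 by sampling noise)
  expect_gte(round(split_rhat(mixed), 2), 1.00)
  expect_lte(split_rhat(mixed), 1.01)

  apart <- cbind(rnorm(500, -10), rnorm(500, 10))
  expect_gt(split_rhat(apart), 5)

  expect_message(r <- split_rhat(matrix(1, 10, 3)), "undefined")
  expect_true(is.na(r))
  expect_error(split_rhat(matrix(1:10, ncol = 1)), "chains")
})

test_that("degenerate all-zero data yield a posterior centred at zero", {
  # scale parameters have no information in all-equal data, so their chains
  # may trip the convergence warning; the intercept is what this checks
  fit <- suppressWarnings(suppressMessages(fit_random_intercept(
    rep(0, 20), rep(paste0("s", 1:10), 2),
    model_spec(n_chains = 2, n_iter = 400, n_warmup = 200, seed = 5))))
  mu <- fit$summary[fit$summary$parameter == "mu", ]
  expect_lt(abs(mu$mean), 0.05)
  expect_lte(mu$ci_low, 0)
  expect_gte(mu$ci_high, 0)
})

test_that("with no between-site variance, tau concentrates near zero and mu tracks the sample mean", {
  set.seed(31)
  y <- rnorm(30, mean = 0.05, sd = 0.1)   # 10 sites x 3 obs, tau = 0 truth
  sites <- rep(paste0("s", 1:10), each = 3)
  fit <- fit_random_intercept(y, sites,
    model_spec(n_chains = 4, n_iter = 1500, n_warmup = 500, seed = 6))
  summ <- fit$summary
  expect_lt(summ$mean[summ$parameter == "tau"], 0.06)
  mu <- summ[summ$parameter == "mu", ]
  expect_gt(mu$ci_high, mean(y))
  expect_lt(mu$ci_low, mean(y))
  expect_true(fit$converged)
})

test_that("under a near-flat prior the intercept matches the conjugate closed form", {
  set.seed(32)
  y <- rnorm(40, 0.05, 0.1)
  fit <- fit_random_intercept(y, paste0("s", 1:40),
    model_spec(n_chains = 4, n_iter = 1500, n_warmup = 500, seed = 7,
               prior_location = 0, prior_scale = 50))
  mu <- fit$summary[fit$summary$parameter == "mu", ]
  # closed form with known total variance var(y) and flat prior:
  # mu | y ~ N(ybar, var(y)/n)
  expect_equal(mu$mean, mean(y), tolerance = 0.005)
  width_closed <- 2 * 1.96 * sd(y) / sqrt(40)
  expect_equal(mu$ci_high - mu$ci_low, width_closed, tolerance = 0.3)
})

test_that("posterior mean of mu lies between the data extremes", {
  set.seed(33)
  for (i in 1:3) {
    y <- rnorm(15, runif(1, -0.2, 0.2), 0.1)
    fit <- suppressWarnings(fit_random_intercept(y, paste0("s", 1:15),
      model_spec(n_chains = 2, n_iter = 600, n_warmup = 300, seed = i)))
    mu <- fit$summary$mean[fit$summary$parameter == "mu"]
    expect_gt(mu, min(y))
    expect_lt(mu, max(y))
  }
})

test_that("doubling the iterations moves summaries only by Monte-Carlo error", {
  set.seed(34)
  y <- rnorm(36, 0.03, 0.08)
  sites <- paste0("s", 1:36)
  f1 <- fit_random_intercept(y, sites,
    model_spec(n_chains = 4, n_iter = 1000, n_warmup = 500, seed = 8))
  f2 <- fit_random_intercept(y, sites,
    model_spec(n_chains = 4, n_iter = 2000, n_warmup = 500, seed = 9))
  m1 <- f1$summary$mean[f1$summary$parameter == "mu"]
  m2 <- f2$summary$mean[f2$summary$parameter == "mu"]
  sd_mu <- sd(as.numeric(f1$draws$mu))
  expect_lt(abs(m1 - m2), 4 * sd_mu / sqrt(200))  # generous ESS floor
})

test_that("the fit is reproducible given the seed", {
  y <- c(0.1, -0.05, 0.02, 0.07, -0.01, 0.04)
  sites <- paste0("s", 1:6)
  spec <- model_spec(n_chains = 2, n_iter = 300, n_warmup = 100, seed = 77)
  f1 <- suppressWarnings(fit_random_intercept(y, sites, spec))
  f2 <- suppressWarnings(fit_random_intercept(y, sites, spec))
  expect_identical(f1$draws$mu, f2$draws$mu)
  expect_identical(f1$summary, f2$summary)
})

test_that("fewer than two sites is an error and convergence is surfaced", {
  expect_error(fit_random_intercept(c(1, 2), c("a", "a"), model_spec()),
               class = "divscale_too_few_sites_error")
  fit <- suppressWarnings(fit_random_intercept(
    rnorm(10), paste0("s", 1:10),
    model_spec(n_chains = 2, n_iter = 200, n_warmup = 100, seed = 1)))
  expect_identical(fit$converged, unname(fit$max_rhat < 1.03))
})

test_that("site-level estimates shrink toward the overall mean", {
  set.seed(35)
  # one extreme site among many consistent ones
  y <- c(rnorm(19 * 3, 0, 0.05), rnorm(3, 0.5, 0.05))
  sites <- rep(paste0("s", 1:20), each = 3)
  fit <- fit_random_intercept(y, sites,
    model_spec(n_chains = 4, n_iter = 1000, n_warmup = 500, seed = 10))
  sl <- site_level_estimates(fit)
  mu <- fit$summary$mean[fit$summary$parameter == "mu"]
  extreme <- sl$mean[sl$site == "s20"]
  raw <- mean(y[sites == "s20"])
  expect_gt(extreme, mu)        # pulled up from the overall mean
  expect_lt(extreme, raw)       # but shrunk below its raw mean
})

test_that("site-level ranking recovers simulated site effects", {
  set.seed(36)
  u <- rnorm(25, 0, 0.1)
  y4 <- as.numeric(vapply(u, function(us) rnorm(4, 0.02 + us, 0.05),
                          numeric(4)))
  sites <- rep(paste0("s", 1:25), each = 4)
  fit <- fit_random_intercept(y4, sites,
    model_spec(n_chains = 4, n_iter = 1000, n_warmup = 500, seed = 11))
  sl <- site_level_estimates(fit)
  est <- sl$mean[match(paste0("s", 1:25), sl$site)]
  expect_gt(cor(est, u, method = "spearman"), 0.5)
})

test_that("the sampler agrees with an independent MCMC engine on the same model", {
  skip_if_not_installed("rjags")
  set.seed(37)
  y <- rnorm(30, 0.05, 0.1)
  sites <- rep(1:15, each = 2)
  fit <- fit_random_intercept(y, paste0("s", sites),
    model_spec(n_chains = 4, n_iter = 3000, n_warmup = 1000, seed = 12))
  m0 <- median(y)
  s0 <- 2.5 * mad(y)
  model <- "model {
    for (i in 1:N) { y[i] ~ dnorm(mu + u[site[i]], 1 / sigma^2) }
    for (s in 1:S) { u[s] ~ dnorm(0, 1 / tau^2) }
    mu ~ dt(m0, 1 / s0^2, 3)
    tau ~ dt(0, 1 / s0^2, 3) T(0,)
    sigma ~ dt(0, 1 / s0^2, 3) T(0,)
  }"
  jm <- rjags::jags.model(textConnection(model),
                          data = list(y = y, site = sites, N = 30, S = 15,
                                      m0 = m0, s0 = s0),
                          n.chains = 3, quiet = TRUE,
                          inits = list(.RNG.name = "base::Mersenne-Twister",
                                       .RNG.seed = 1))
  invisible(rjags::jags.samples(jm, "mu", 1000))  # burn-in
  samp <- rjags::coda.samples(jm, c("mu", "tau", "sigma"), 4000)
  ref <- summary(samp)$statistics
  ours <- fit$summary
  expect_lt(abs(ours$mean[ours$parameter == "mu"] - ref["mu", "Mean"]),
            0.01)
  expect_lt(abs(ours$mean[ours$parameter == "sigma"] - ref["sigma", "Mean"]),
            0.01)
  expect_lt(abs(ours$mean[ours$parameter == "tau"] - ref["tau", "Mean"]),
            0.01)
})

test_that("predictive summary brackets the observed statistics for well-specified data", {
  set.seed(38)
  y <- rnorm(60, 0.03, 0.1)
  fit <- fit_random_intercept(y, rep(paste0("s", 1:20), each = 3),
    model_spec(n_chains = 2, n_iter = 800, n_warmup = 400, seed = 13))
  ps <- predictive_summary(fit)
  expect_equal(ps$statistic, c("mean", "sd"))
  expect_true(all(ps$rep_q025 <= ps$observed & ps$observed <= ps$rep_q975))
})
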
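#' Sampler specification for the random-intercept model
#'
#' Mirrors the fitting defaults of Bayesian mixed-model practice for log
#' response ratios: weakly informative, data-scaled priors — the location
#' gets a Student-t prior centred on the sample median with scale
#' `2.5 * mad(y)` and 3 degrees of freedom, and both standard deviations get
#' half-t priors with the same scale and df. When `mad(y)` is zero
#' (degenerate all-equal data) the scale falls back to 2.5 so the prior
#' stays proper.
#'
#' @param n_chains Number of chains (>= 2; default 6).
#' @param n_iter Iterations per chain including warmup (default 3000).
#' @param n_warmup Warmup iterations discarded per chain (default 1000).
#' @param seed Integer seed; every chain derives its own stream from it.
#' @param prior_df Degrees of freedom of the t/half-t priors (default 3).
#' @param prior_location Optional fixed prior centre (default: median of y).
#' @param prior_scale Optional fixed prior scale (default: 2.5 * mad(y)).
#' @return A `model_spec` list.
#' @export
model_spec <- function(n_chains = 6, n_iter = 3000, n_warmup = 1000,
                       seed = 1, prior_df = 3,
                       prior_location = NULL, prior_scale = NULL) {
  stopifnot(n_chains >= 2, n_warmup < n_iter, n_iter >= 4, prior_df > 0)
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 n_warmup = as.integer(n_warmup),
                 seed = as.integer(seed), prior_df = prior_df,
                 prior_location = prior_location,
                 prior_scale = prior_scale),
            class = "model_spec")
}

# Inverse-gamma draw, shape/rate parameterization.
rinvgamma1 <- function(shape, rate) 1 / rgamma(1L, shape = shape, rate = rate)

# One MCMC chain for y_i = mu + u_site(i) + eps_i, u ~ N(0, tau^2),
# eps ~ N(0, sigma^2). t prior on mu via a latent Gamma mixing precision;
# half-t(nu, s0) priors on tau and sigma entering the Metropolis target
# through their exact densities.
#
# mu and (tau, sigma) are updated with the site effects integrated out
# (per-site means ybar_s ~ N(mu, tau^2 + sigma^2/n_s)): with one observation
# per site only tau^2 + sigma^2 is well identified and plain conjugate
# updates crawl along that ridge, while the marginalized random-walk
# Metropolis step traverses it. u is then redrawn conjugately.
run_gibbs_chain <- function(y, site_idx, n_sites, n_iter, n_warmup,
                            m0, s0, nu, chain_seed) {
  set.seed(chain_seed)
  n <- length(y)
  n_s <- tabulate(site_idx, nbins = n_sites)
  ybar <- as.numeric(rowsum(y, site_idx)) / n_s
  ss_within <- sum((y - ybar[site_idx])^2)

  # marginal log-likelihood (u integrated out) for given mu, tau^2, sigma^2
  marg_loglik <- function(mu, tau2, sigma2) {
    v <- tau2 + sigma2 / n_s
    -0.5 * ((n - n_sites) * log(sigma2) + ss_within / sigma2 +
              sum(log(v)) + sum((ybar - mu)^2 / v))
  }
  # unnormalized log density of a variance whose sd is half-t(nu, s0)
  log_half_t_var <- function(x) {
    -(nu + 1) / 2 * log1p(x / (nu * s0^2)) - 0.5 * log(x)
  }

  mu <- stats::rnorm(1, m0, s0 / 4)
  tau2 <- (s0 / 4)^2
  sigma2 <- (s0 / 4)^2
  lambda <- 1
  step <- 0.3
  keep <- n_iter - n_warmup
  out_mu <- numeric(keep)
  out_tau <- numeric(keep)
  out_sigma <- numeric(keep)
  out_u <- matrix(0, keep, n_sites)
  for (it in seq_len(n_iter)) {
    # overall intercept, u marginalized (t prior = scale mixture of normals)
    v <- tau2 + sigma2 / n_s
    prec_mu <- sum(1 / v) + lambda / s0^2
    mean_mu <- (sum(ybar / v) + lambda * m0 / s0^2) / prec_mu
    mu <- stats::rnorm(1, mean_mu, sqrt(1 / prec_mu))
    lambda <- rgamma(1L, shape = (nu + 1) / 2,
                     rate = (nu + ((mu - m0) / s0)^2) / 2)
    # (tau, sigma) Metropolis with u marginalized. Two move types:
    # a log-scale random walk on both variances (moves the overall level)
    # and a rotation of the variance split at fixed total (traverses the
    # tau^2 + sigma^2 ridge that single-observation sites leave flat).
    log_target <- function(t2, s2) {
      marg_loglik(mu, t2, s2) + log_half_t_var(t2) + log_half_t_var(s2)
    }
    cur <- log_target(tau2, sigma2)
    for (rep in 1:3) {
      # scale move (log-sd random walk; Jacobian log t2 + log s2)
      th_t <- 0.5 * log(tau2) + stats::rnorm(1, 0, step)
      th_s <- 0.5 * log(sigma2) + stats::rnorm(1, 0, step)
      pt2 <- exp(2 * th_t)
      ps2 <- exp(2 * th_s)
      lr <- (log_target(pt2, ps2) + log(pt2) + log(ps2)) -
        (cur + log(tau2) + log(sigma2))
      if (is.finite(lr) && log(runif(1)) < lr) {
        tau2 <- pt2
        sigma2 <- ps2
        cur <- log_target(tau2, sigma2)
      }
      # ridge move: independence proposal on the variance share at fixed
      # total (stationary density in the share is target * total, and the
      # total cancels)
      tot <- tau2 + sigma2
      rho_p <- runif(1)
      pt2 <- rho_p * tot
      ps2 <- (1 - rho_p) * tot
      lr <- log_target(pt2, ps2) - cur
      if (is.finite(lr) && log(runif(1)) < lr) {
        tau2 <- pt2
        sigma2 <- ps2
        cur <- log_target(tau2, sigma2)
      }
    }
    # site effects, conjugate given everything else
    resid_site <- as.numeric(rowsum(y - mu, site_idx))
    prec_u <- n_s / sigma2 + 1 / tau2
    u <- stats::rnorm(n_sites, (resid_site / sigma2) / prec_u,
                      sqrt(1 / prec_u))
    if (it > n_warmup) {
      k <- it - n_warmup
      out_mu[k] <- mu
      out_tau[k] <- sqrt(tau2)
      out_sigma[k] <- sqrt(sigma2)
      out_u[k, ] <- u
    }
  }
  list(mu = out_mu, tau = out_tau, sigma = out_sigma, u = out_u)
}

#' Fit the Bayesian random-intercept model for a diversity-change response
#'
#' Estimates `y_i = mu + u_site(i) + eps_i` with `u ~ Normal(0, tau^2)` and
#' `eps ~ Normal(0, sigma^2)` — the hierarchical "change ~ 1 + (1 | site)"
#' model — by a marginalized Gibbs sampler (conjugate updates for the
#' intercept and site effects, Metropolis updates for the two scales with
#' the site effects integrated out) under the data-scaled t priors of
#' [model_spec()]. Sites may contribute one observation (gamma- and
#' beta-scale responses) or several (per-block alpha responses); with one
#' observation per site, `tau` and `sigma` are only jointly weakly
#' identified and the priors do the regularizing. Split-Rhat is attached per
#' parameter and a warning is raised if any exceeds the 1.03 convergence
#' bound.
#'
#' @param values Numeric response vector (finite).
#' @param site_ids Site identifier per observation (>= 2 distinct sites).
#' @param spec A [model_spec].
#' @return A `posterior_fit` list: `draws` (per-chain), `summary` tibble
#'   (parameter, mean, ci_low, ci_high, rhat), `site_levels` tibble
#'   (per-site posterior of `mu + u_s`), `converged`, `max_rhat`,
#'   `n_obs`, `sites`.
#' @export
fit_random_intercept <- function(values, site_ids, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  if (any(!is.finite(values))) abort("values must be finite")
  sites <- unique(as.character(site_ids))
  if (length(sites) < 2) {
    abort("at least 2 distinct sites are required",
          class = "divscale_too_few_sites_error")
  }
  site_idx <- match(as.character(site_ids), sites)
  m0 <- spec$prior_location %||% median(values)
  s0 <- spec$prior_scale %||% (2.5 * mad(values))
  if (!is.finite(s0) || s0 <= 0) s0 <- 2.5

  chains <- lapply(seq_len(spec$n_chains), function(ch) {
    run_gibbs_chain(values, site_idx, length(sites),
                    spec$n_iter, spec$n_warmup,
                    m0, s0, spec$prior_df,
                    chain_seed = derive_seed(spec$seed, ch))
  })

  draw_mat <- function(field) vapply(chains, `[[`, numeric(spec$n_iter - spec$n_warmup), field)
  mu_m <- draw_mat("mu")
  tau_m <- draw_mat("tau")
  sigma_m <- draw_mat("sigma")

  summarize_par <- function(m, name) {
    d <- as.numeric(m)
    tibble::tibble(parameter = name, mean = mean(d),
                   ci_low = unname(quantile(d, 0.025)),
                   ci_high = unname(quantile(d, 0.975)),
                   rhat = split_rhat(m))
  }
  summ <- dplyr::bind_rows(summarize_par(mu_m, "mu"),
                           summarize_par(tau_m, "tau"),
                           summarize_par(sigma_m, "sigma"))

  # site-level effects mu + u_s, pooled across chains
  site_rows <- lapply(seq_along(sites), function(s) {
    d <- as.numeric(mu_m) +
      as.numeric(vapply(chains, function(ch) ch$u[, s],
                        numeric(spec$n_iter - spec$n_warmup)))
    tibble::tibble(site = sites[s], mean = mean(d),
                   ci_low = unname(quantile(d, 0.025)),
                   ci_high = unname(quantile(d, 0.975)))
  })

  max_rhat <- max(summ$rhat, na.rm = TRUE)
  converged <- is.finite(max_rhat) && max_rhat < 1.03
  if (!converged) {
    warn(paste0("convergence warning: max split-Rhat = ",
                format(max_rhat, digits = 4), " (bound 1.03)"))
  }
  structure(list(draws = list(mu = mu_m, tau = tau_m, sigma = sigma_m,
                              u = lapply(chains, `[[`, "u")),
                 summary = summ,
                 site_levels = dplyr::bind_rows(site_rows),
                 converged = converged, max_rhat = max_rhat,
                 n_obs = length(values), sites = sites, spec = spec,
                 values = values, site_idx = site_idx),
            class = "posterior_fit")
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat("<posterior_fit> ", x$n_obs, " obs, ", length(x$sites), " sites, ",
      x$spec$n_chains, " chains x ", x$spec$n_iter, " iter (",
      x$spec$n_warmup, " warmup); max split-Rhat ",
      format(x$max_rhat, digits = 4), "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Split-chain potential scale reduction (split-Rhat)
#'
#' Each chain is halved; the statistic compares between- and within-halfchain
#' variance (`sqrt(((n-1)/n * W + B/n) / W)`). Values near 1 indicate
#' convergence; the pipeline's acceptance bound is 1.03.
#'
#' @param chains A matrix of posterior draws, iterations x chains (>= 2
#'   chains, >= 4 draws each).
#' @return The split-Rhat value, or `NA` (with a message) when the
#'   within-chain variance is zero everywhere and the statistic is
#'   undefined.
#' @export
split_rhat <- function(chains) {
  chains <- as.matrix(chains)
  n <- nrow(chains)
  if (ncol(chains) < 2 || n < 4) {
    abort("split_rhat needs >= 2 chains with >= 4 draws each")
  }
  half <- floor(n / 2)
  split <- cbind(chains[seq_len(half), , drop = FALSE],
                 chains[(n - half + 1):n, , drop = FALSE])
  m <- ncol(split)
  means <- colMeans(split)
  vars <- apply(split, 2, stats::var)
  w <- mean(vars)
  if (w == 0) {
    inform("split_rhat undefined: zero within-chain variance in every chain")
    return(NA_real_)
  }
  b <- half * stats::var(means)
  var_plus <- (half - 1) / half * w + b / half
  sqrt(var_plus / w)
}

#' Per-site posterior estimates of diversity change
#'
#' Posterior mean and 95% equal-tailed credible interval of `mu + u_s` for
#' every site — the site-level expected change, partially pooled toward the
#' overall mean (shrinkage grows as the between-site sd `tau` approaches 0).
#'
#' @param fit A `posterior_fit`.
#' @return A tibble: `site`, `mean`, `ci_low`, `ci_high`.
#' @export
site_level_estimates <- function(fit) {
  stopifnot(inherits(fit, "posterior_fit"))
  fit$site_levels
}

#' Basic posterior-predictive summary
#'
#' Compares the observed mean and standard deviation of the response with
#' their distribution over replicated datasets drawn from the posterior.
#'
#' @param fit A `posterior_fit`.
#' @param n_draws Number of posterior draws to replicate (default 500).
#' @return A tibble with observed value and replicated 2.5/50/97.5%
#'   quantiles for the mean and sd statistics.
#' @export
predictive_summary <- function(fit, n_draws = 500) {
  stopifnot(inherits(fit, "posterior_fit"))
  kept <- length(fit$draws$mu)
  set.seed(derive_seed(fit$spec$seed, 99991L))
  take <- sample.int(kept, min(n_draws, kept))
  n_chain_draws <- nrow(fit$draws$mu)
  rep_stats <- vapply(take, function(k) {
    ch <- ((k - 1) %/% n_chain_draws) + 1
    it <- ((k - 1) %% n_chain_draws) + 1
    mu <- fit$draws$mu[it, ch]
    sigma <- fit$draws$sigma[it, ch]
    u <- fit$draws$u[[ch]][it, ]
    y_rep <- stats::rnorm(fit$n_obs, mu + u[fit$site_idx], sigma)
    c(mean(y_rep), stats::sd(y_rep))
  }, numeric(2))
  tibble::tibble(
    statistic = c("mean", "sd"),
    observed = c(mean(fit$values), stats::sd(fit$values)),
    rep_q025 = apply(rep_stats, 1, quantile, 0.025),
    rep_q50 = apply(rep_stats, 1, quantile, 0.5),
    rep_q975 = apply(rep_stats, 1, quantile, 0.975))
}
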
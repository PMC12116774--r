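#' Configuration for simulating one site
#'
#' The generator emulates a blocked nutrient-addition site: each block holds
#' one Control and one NPK 1 m x 1 m subplot. The species pool mixes
#' `n_widespread` species present in every block with `n_restricted`
#' spatially restricted species unique to each block — the two occupancy
#' classes whose differential gains and losses generate the six
#' homogenization/differentiation scenarios. NPK assemblages derive from the
#' Control ones by Bernoulli losses (site-wide for widespread species,
#' per-block for restricted ones) and by gains drawn from treatment-only
#' candidate pools. Covers are log-normal; per-subplot totals may exceed
#' 100%.
#'
#' @param n_blocks Number of blocks (default 3).
#' @param n_widespread Widespread species present in all blocks (default 12).
#' @param n_restricted Restricted species unique to each block (default 6
#'   per block).
#' @param cover_meanlog,cover_sdlog Log-normal cover parameters (defaults
#'   1.5 and 1.0 — percent covers mostly between 1 and 30).
#' @param p_loss_restricted Probability each restricted species is lost from
#'   its block under NPK.
#' @param p_loss_widespread Probability each widespread species is lost from
#'   the whole site under NPK.
#' @param gain_pool_restricted,p_gain_restricted Per-block pool size and
#'   inclusion probability of new block-unique species under NPK.
#' @param gain_pool_widespread,p_gain_widespread Pool size and inclusion
#'   probability of new species gained in every block under NPK.
#' @param frac_native Fraction of species labelled native (default 0.8).
#' @param lifeform_probs Named probabilities over forb/graminoid/legume/woody.
#' @param allow_empty_subplots Keep subplots that lose all species (default
#'   FALSE: one control species is retained so every subplot stays
#'   non-empty).
#' @param year_trt Treatment year of the snapshot (default 4).
#' @return A `site_sim_config` list.
#' @export
site_sim_config <- function(n_blocks = 3, n_widespread = 12,
                            n_restricted = 6,
                            cover_meanlog = 1.5, cover_sdlog = 1.0,
                            p_loss_restricted = 0, p_loss_widespread = 0,
                            gain_pool_restricted = 0, p_gain_restricted = 0,
                            gain_pool_widespread = 0, p_gain_widespread = 0,
                            frac_native = 0.8,
                            lifeform_probs = c(forb = 0.5, graminoid = 0.3,
                                               legume = 0.12, woody = 0.08),
                            allow_empty_subplots = FALSE, year_trt = 4) {
  probs <- c(p_loss_restricted, p_loss_widespread, p_gain_restricted,
             p_gain_widespread, frac_native)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (n_widespread + n_restricted < 1) abort("species pool is empty")
  if (p_gain_restricted > 0 && gain_pool_restricted == 0) {
    abort("p_gain_restricted > 0 requires a non-empty restricted gain pool")
  }
  if (p_gain_widespread > 0 && gain_pool_widespread == 0) {
    abort("p_gain_widespread > 0 requires a non-empty widespread gain pool")
  }
  structure(list(n_blocks = n_blocks, n_widespread = n_widespread,
                 n_restricted = n_restricted,
                 cover_meanlog = cover_meanlog, cover_sdlog = cover_sdlog,
                 p_loss_restricted = p_loss_restricted,
                 p_loss_widespread = p_loss_widespread,
                 gain_pool_restricted = gain_pool_restricted,
                 p_gain_restricted = p_gain_restricted,
                 gain_pool_widespread = gain_pool_widespread,
                 p_gain_widespread = p_gain_widespread,
                 frac_native = frac_native, lifeform_probs = lifeform_probs,
                 allow_empty_subplots = allow_empty_subplots,
                 year_trt = year_trt),
            class = "site_sim_config")
}

# Species attribute labels drawn once per species.
draw_species_attrs <- function(n, cfg) {
  lf <- names(cfg$lifeform_probs)
  tibble::tibble(
    is_native = ifelse(runif(n) < cfg$frac_native, "native", "non-native"),
    lifeform = sample(lf, n, replace = TRUE, prob = cfg$lifeform_probs))
}

#' Simulate one paired Control/NPK site
#'
#' Draws the Control assemblage from the configured pool, derives the NPK
#' assemblage by the configured losses and gains, and attaches log-normal
#' covers. Reproducible: the same seed yields an identical table.
#'
#' @param cfg A [site_sim_config].
#' @param seed Integer seed.
#' @param site_id Site label (default `"site_1"`).
#' @return A [cover_table] for one site, both treatments, one year.
#' @export
generate_site <- function(cfg, seed, site_id = "site_1") {
  stopifnot(inherits(cfg, "site_sim_config"))
  set.seed(seed)
  nb <- cfg$n_blocks
  blocks <- seq_len(nb)

  sp <- list()
  if (cfg$n_widespread > 0) {
    sp$wide <- tibble::tibble(
      taxon = sprintf("%s_w%02d", site_id, seq_len(cfg$n_widespread)),
      draw_species_attrs(cfg$n_widespread, cfg))
  }
  if (cfg$n_restricted > 0) {
    sp$restricted <- dplyr::bind_rows(lapply(blocks, function(b) {
      tibble::tibble(
        taxon = sprintf("%s_b%d_r%02d", site_id, b,
                        seq_len(cfg$n_restricted)),
        block = b, draw_species_attrs(cfg$n_restricted, cfg))
    }))
  }
  if (cfg$gain_pool_widespread > 0) {
    sp$gain_wide <- tibble::tibble(
      taxon = sprintf("%s_gw%02d", site_id, seq_len(cfg$gain_pool_widespread)),
      draw_species_attrs(cfg$gain_pool_widespread, cfg))
  }
  if (cfg$gain_pool_restricted > 0) {
    sp$gain_restricted <- dplyr::bind_rows(lapply(blocks, function(b) {
      tibble::tibble(
        taxon = sprintf("%s_b%d_gr%02d", site_id, b,
                        seq_len(cfg$gain_pool_restricted)),
        block = b, draw_species_attrs(cfg$gain_pool_restricted, cfg))
    }))
  }

  # membership realizations
  wide_lost <- if (cfg$n_widespread > 0) {
    runif(cfg$n_widespread) < cfg$p_loss_widespread
  } else logical(0)
  gained_wide <- if (cfg$gain_pool_widespread > 0) {
    runif(cfg$gain_pool_widespread) < cfg$p_gain_widespread
  } else logical(0)

  rows <- list()
  add_rows <- function(taxa, attrs, block, trt) {
    if (length(taxa) == 0) return(NULL)
    tibble::tibble(site = site_id, block = block, trt = trt,
                   year_trt = cfg$year_trt, taxon = taxa,
                   cover = rlnorm(length(taxa), cfg$cover_meanlog,
                                  cfg$cover_sdlog),
                   is_native = attrs$is_native, lifeform = attrs$lifeform)
  }
  for (b in blocks) {
    rb <- if (!is.null(sp$restricted)) {
      sp$restricted[sp$restricted$block == b, ]
    } else NULL
    ctrl_taxa <- c(sp$wide$taxon, rb$taxon)
    ctrl_attrs <- dplyr::bind_rows(sp$wide[c("is_native", "lifeform")],
                                   rb[c("is_native", "lifeform")])
    rows[[length(rows) + 1L]] <- add_rows(ctrl_taxa, ctrl_attrs, b, "Control")

    restricted_kept <- if (!is.null(rb) && nrow(rb) > 0) {
      runif(nrow(rb)) >= cfg$p_loss_restricted
    } else logical(0)
    grb <- if (!is.null(sp$gain_restricted)) {
      sp$gain_restricted[sp$gain_restricted$block == b, ]
    } else NULL
    gained_restricted <- if (!is.null(grb) && nrow(grb) > 0) {
      runif(nrow(grb)) < cfg$p_gain_restricted
    } else logical(0)

    npk_taxa <- c(sp$wide$taxon[!wide_lost],
                  rb$taxon[restricted_kept],
                  sp$gain_wide$taxon[gained_wide],
                  grb$taxon[gained_restricted])
    npk_attrs <- dplyr::bind_rows(
      sp$wide[!wide_lost, c("is_native", "lifeform")],
      rb[restricted_kept, c("is_native", "lifeform")],
      sp$gain_wide[gained_wide, c("is_native", "lifeform")],
      grb[gained_restricted, c("is_native", "lifeform")])
    if (length(npk_taxa) == 0 && !cfg$allow_empty_subplots) {
      npk_taxa <- ctrl_taxa[1]
      npk_attrs <- ctrl_attrs[1, ]
    }
    rows[[length(rows) + 1L]] <- add_rows(npk_taxa, npk_attrs, b, "NPK")
  }
  cover_table(dplyr::bind_rows(rows))
}

# E[log(base + sign * X)] for X ~ Binomial(size, prob), by enumeration.
expected_log_binom <- function(base, size, prob, sign = 1L) {
  if (size == 0 || prob == 0) return(log(base))
  k <- 0:size
  sum(stats::dbinom(k, size, prob) * log(base + sign * k))
}

# Expected per-site log response ratios under pure restricted-species loss
# (prob p) or pure restricted-species gain (pool g_pool per block, rate r).
expected_deltas_loss <- function(p, W, R, nb = 3) {
  da <- expected_log_binom(W + R, R, p, -1L) - log(W + R)
  dg <- expected_log_binom(W + nb * R, nb * R, p, -1L) - log(W + nb * R)
  c(delta_alpha_bar = da, delta_gamma = dg, delta_beta = dg - da)
}
expected_deltas_gain <- function(r, W, R, g_pool, nb = 3) {
  da <- expected_log_binom(W + R, g_pool, r, 1L) - log(W + R)
  dg <- expected_log_binom(W + nb * R, nb * g_pool, r, 1L) - log(W + nb * R)
  c(delta_alpha_bar = da, delta_gamma = dg, delta_beta = dg - da)
}

# Invert E[delta_beta] = target over the loss probability (target < 0) or
# the gain rate (target > 0). Exact (binomial enumeration), so realized site
# delta_beta is unbiased for its target. Targets beyond the attainable range
# are clamped to the endpoint.
calibrate_site_param <- function(target, W, R, g_pool, nb = 3) {
  if (target == 0) return(list(mechanism = "none", param = 0))
  if (target < 0) {
    lo <- expected_deltas_loss(1, W, R, nb)[["delta_beta"]]
    if (target <= lo) return(list(mechanism = "loss", param = 1))
    p <- stats::uniroot(function(p) {
      expected_deltas_loss(p, W, R, nb)[["delta_beta"]] - target
    }, c(0, 1), tol = 1e-10)$root
    list(mechanism = "loss", param = p)
  } else {
    hi <- expected_deltas_gain(1, W, R, g_pool, nb)[["delta_beta"]]
    if (target >= hi) return(list(mechanism = "gain", param = 1))
    r <- stats::uniroot(function(r) {
      expected_deltas_gain(r, W, R, g_pool, nb)[["delta_beta"]] - target
    }, c(0, 1), tol = 1e-10)$root
    list(mechanism = "gain", param = r)
  }
}

#' Preset site configurations realizing each change scenario
#'
#' Returns a [site_sim_config] whose generated sites classify as the target
#' scenario in at least 80% of seeded draws. The mechanisms follow the
#' occupancy logic of the framework: losing restricted species removes more
#' diversity from the pooled (gamma) than the subplot (alpha) scale
#' (scenario III), losing widespread species does the reverse (IV); gains
#' mirror the losses (widespread gains -> I, restricted gains -> VI); II
#' combines heavy restricted losses with widespread gains, V widespread
#' losses with restricted gains.
#'
#' @param target One of `"I"`, `"II"`, `"III"`, `"IV"`, `"V"`, `"VI"`.
#' @return A `site_sim_config`.
#' @export
scenario_preset <- function(target) {
  switch(target,
    I = site_sim_config(gain_pool_widespread = 8, p_gain_widespread = 0.8),
    II = site_sim_config(p_loss_restricted = 0.9,
                         gain_pool_widespread = 10, p_gain_widespread = 0.8),
    III = site_sim_config(p_loss_restricted = 0.5),
    IV = site_sim_config(p_loss_widespread = 0.4),
    V = site_sim_config(n_widespread = 20, p_loss_widespread = 0.45,
                        gain_pool_restricted = 8, p_gain_restricted = 0.6),
    VI = site_sim_config(gain_pool_restricted = 6, p_gain_restricted = 0.6),
    abort(paste0("unknown scenario target: ", target)))
}

#' Configuration for simulating a whole multi-site study
#'
#' @param n_sites Number of sites (default 72).
#' @param mu True overall mean of the site-level expected beta-scale log
#'   response ratio (default 0.03).
#' @param tau Between-site standard deviation of that expectation (default
#'   0.05).
#' @param n_blocks Blocks per site (default 3).
#' @param n_widespread,n_restricted Pool structure passed to each site
#'   (defaults 12 and 6).
#' @param gain_pool Per-block candidate pool for calibrated gains (default
#'   15).
#' @param frac_native,lifeform_probs Species-group label generators.
#' @param n_year14_sites Number of sites that also receive an independent
#'   year-14 snapshot with the same calibrated effect (default 0).
#' @return A `study_sim_config` list.
#' @export
study_sim_config <- function(n_sites = 72, mu = 0.03, tau = 0.05,
                             n_blocks = 3, n_widespread = 12,
                             n_restricted = 6, gain_pool = 15,
                             frac_native = 0.8,
                             lifeform_probs = c(forb = 0.5, graminoid = 0.3,
                                                legume = 0.12, woody = 0.08),
                             n_year14_sites = 0) {
  stopifnot(n_sites >= 2, tau >= 0, n_year14_sites <= n_sites)
  structure(list(n_sites = n_sites, mu = mu, tau = tau, n_blocks = n_blocks,
                 n_widespread = n_widespread, n_restricted = n_restricted,
                 gain_pool = gain_pool, frac_native = frac_native,
                 lifeform_probs = lifeform_probs,
                 n_year14_sites = n_year14_sites),
            class = "study_sim_config")
}

#' Simulate a multi-site nutrient-addition study with known effects
#'
#' Each site draws a target beta-scale log response ratio from
#' `Normal(mu, tau^2)` and realizes it through calibrated losses (negative
#' targets, restricted-species losses) or gains (positive targets,
#' restricted-species gains): the loss/gain probability is found by exactly
#' inverting the closed-form expectation of the realized `delta_beta` under
#' the binomial mechanism, so the realized site values are unbiased for
#' their targets. Site metadata (coordinates, per-block coordinates, annual
#' PET/precipitation, control biomass, herbivore importance values) is
#' generated alongside so the covariate analyses can run end to end.
#'
#' @param cfg A [study_sim_config].
#' @param seed Integer seed; all site-level randomness derives from it.
#' @return A list: `table` (a [cover_table] with site and block metadata),
#'   `site_env` (per site x year PET/precip/biomass), `herbivores`
#'   (per-herbivore importance rows), `truth` (per-site targets, mechanisms
#'   and expected deltas plus the study-level `mu`, `tau`).
#' @export
generate_study <- function(cfg, seed) {
  stopifnot(inherits(cfg, "study_sim_config"))
  W <- cfg$n_widespread
  R <- cfg$n_restricted
  site_ids <- sprintf("site_%02d", seq_len(cfg$n_sites))

  set.seed(derive_seed(seed, 0L))
  targets <- rnorm(cfg$n_sites, cfg$mu, cfg$tau)
  lat <- runif(cfg$n_sites, -40, 60)
  lon <- runif(cfg$n_sites, -125, 40)

  tables <- list()
  truth_rows <- list()
  env_rows <- list()
  herb_rows <- list()
  block_rows <- list()
  for (i in seq_len(cfg$n_sites)) {
    cal <- calibrate_site_param(targets[i], W, R, cfg$gain_pool,
                                nb = cfg$n_blocks)
    site_cfg <- site_sim_config(
      n_blocks = cfg$n_blocks, n_widespread = W, n_restricted = R,
      p_loss_restricted = if (cal$mechanism == "loss") cal$param else 0,
      gain_pool_restricted = if (cal$mechanism == "gain") cfg$gain_pool else 0,
      p_gain_restricted = if (cal$mechanism == "gain") cal$param else 0,
      frac_native = cfg$frac_native, lifeform_probs = cfg$lifeform_probs)
    tables[[length(tables) + 1L]] <-
      generate_site(site_cfg, derive_seed(seed, i), site_ids[i])
    if (i <= cfg$n_year14_sites) {
      site_cfg14 <- site_cfg
      site_cfg14$year_trt <- 14
      tables[[length(tables) + 1L]] <-
        generate_site(site_cfg14, derive_seed(seed, 100000L + i), site_ids[i])
    }
    exp_d <- switch(cal$mechanism,
      loss = expected_deltas_loss(cal$param, W, R, cfg$n_blocks),
      gain = expected_deltas_gain(cal$param, W, R, cfg$gain_pool,
                                  cfg$n_blocks),
      none = c(delta_alpha_bar = 0, delta_gamma = 0, delta_beta = 0))
    truth_rows[[i]] <- tibble::tibble(
      site = site_ids[i], target_delta_beta = targets[i],
      mechanism = cal$mechanism, param = cal$param,
      expected_delta_alpha_bar = exp_d[["delta_alpha_bar"]],
      expected_delta_gamma = exp_d[["delta_gamma"]],
      expected_delta_beta = exp_d[["delta_beta"]])

    set.seed(derive_seed(seed, 200000L + i))
    precip <- rlnorm(5, log(700), 0.25)
    env_rows[[i]] <- tibble::tibble(
      site = site_ids[i], year = 0:4,
      pet = rlnorm(5, log(800), 0.2), precip = precip,
      biomass_g_per_0.2m2 = rlnorm(5, log(80), 0.3))
    n_herb <- sample(0:4, 1)
    if (n_herb > 0) {
      herb_rows[[length(herb_rows) + 1L]] <- tibble::tibble(
        site = site_ids[i], importance = sample(1:5, n_herb, replace = TRUE))
    }
    # blocks scattered within ~1 km of the site centre
    block_rows[[i]] <- tibble::tibble(
      site = site_ids[i], block = seq_len(cfg$n_blocks),
      block_lat = lat[i] + runif(cfg$n_blocks, -0.005, 0.005),
      block_lon = lon[i] + runif(cfg$n_blocks, -0.005, 0.005))
  }

  records <- dplyr::bind_rows(lapply(tables, as.data.frame))
  table <- cover_table(records,
                       site_meta = tibble::tibble(site = site_ids,
                                                  lat = lat, lon = lon),
                       block_meta = dplyr::bind_rows(block_rows))
  list(table = table,
       site_env = dplyr::bind_rows(env_rows),
       herbivores = if (length(herb_rows)) dplyr::bind_rows(herb_rows) else
         tibble::tibble(site = character(0), importance = integer(0)),
       truth = list(mu = cfg$mu, tau = cfg$tau,
                    sites = dplyr::bind_rows(truth_rows)))
}
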
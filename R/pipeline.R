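#' Configuration of a full scale-diversity analysis
#'
#' @param year Analysis year (`year_trt`, default 4: treatments applied for
#'   at least four years).
#' @param n_blocks Blocks selected per site (default 3).
#' @param q_orders Hill orders to analyse (default `c(0, 1, 2)`).
#' @param groups Species groups to analyse (default the entire community,
#'   the native/non-native pair and the four lifeforms).
#' @param model A [model_spec] used for every posterior fit.
#' @param moran_permutations Permutations for the Moran's I tests (default
#'   999).
#' @param seed Master seed; model fits and permutation tests derive their
#'   own streams from it.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(year = 4, n_blocks = 3, q_orders = c(0, 1, 2),
                            groups = c("all", "native", "non-native", "forb",
                                       "graminoid", "legume", "woody"),
                            model = model_spec(),
                            moran_permutations = 999, seed = 1) {
  stopifnot(inherits(model, "model_spec"), n_blocks >= 2)
  structure(list(year = year, n_blocks = n_blocks, q_orders = q_orders,
                 groups = groups, model = model,
                 moran_permutations = moran_permutations,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

# Stable per-fit seed: one slot per (group, q, response).
fit_seed <- function(cfg, group, q, response) {
  ix <- match(group, cfg$groups) * 100L + match(q, cfg$q_orders) * 10L +
    match(response, c("delta_alpha", "delta_gamma", "delta_beta"))
  derive_seed(cfg$seed, 300000L + ix)
}

#' Run the full scale-dependent diversity-change analysis
#'
#' Orchestrates the whole analysis on a long-format cover table: block
#' selection, per-group log(0) filtering, Hill diversity at both scales, log
#' response ratios and scenario classification, three random-intercept model
#' fits (per-block `delta_alpha`, per-site `delta_gamma`, per-site
#' `delta_beta`) for every group x order combination, site covariates with
#' per-covariate regressions, and Moran's I spatial autocorrelation of the
#' community-level changes. Deterministic given `cfg$seed`.
#'
#' @param table A [cover_table].
#' @param cfg An [analysis_config].
#' @param site_env Optional per site x year environment table (see
#'   [site_covariates()]).
#' @param herbivores Optional herbivore importance table.
#' @return A `result_bundle` list: `deltas` (tidy tibble over group x q x
#'   site), `scenario_counts`, `fits`, `posterior_summary`, `site_levels`,
#'   `covariates`, `covariate_regressions`, `moran`, `exclusions`,
#'   `all_converged`, `config`.
#' @export
run_pipeline <- function(table, cfg = analysis_config(), site_env = NULL,
                         herbivores = NULL) {
  stopifnot(inherits(table, "cover_table"), inherits(cfg, "analysis_config"))
  snap <- table[table$year_trt == cfg$year, ]
  attr(snap, "site_meta") <- attr(table, "site_meta")
  attr(snap, "block_meta") <- attr(table, "block_meta")
  class(snap) <- class(table)
  if (nrow(snap) == 0) {
    abort(paste0("no records at analysis year ", cfg$year),
          class = "divscale_empty_result_error")
  }
  # a site qualifies only with both treatments present in the analysis year
  both <- tapply(snap$trt, snap$site, function(tr) all(TREATMENTS %in% tr))
  snap <- snap[snap$site %in% names(both)[both], ]
  class(snap) <- class(table)
  selected <- select_blocks(snap, cfg$n_blocks)
  exclusions <- list(too_few_blocks = attr(selected, "dropped_sites"))

  deltas_all <- list()
  counts <- list()
  fits <- list()
  summ_rows <- list()
  site_rows <- list()
  for (g in cfg$groups) {
    fg <- filter_group(selected, g)
    exclusions[[paste0("group_", g)]] <- fg$excluded_sites
    if (length(unique(fg$table$site)) < 2) {
      inform(paste0("group ", g,
                    ": fewer than 2 retained sites, models skipped"))
      next
    }
    for (q in cfg$q_orders) {
      div <- scale_diversity(fg$table, cfg$year, q)
      dl <- delta_table(div)
      dl$group <- g
      deltas_all[[paste0(g, "_q", q)]] <- dl
      counts[[g]][[paste0("q", q)]] <- scenario_counts(dl)
      responses <- list(
        delta_alpha = list(values = unlist(dl$delta_alpha),
                           sites = rep(dl$site,
                                       vapply(dl$delta_alpha, length, 1L))),
        delta_gamma = list(values = dl$delta_gamma, sites = dl$site),
        delta_beta = list(values = dl$delta_beta, sites = dl$site))
      for (resp in names(responses)) {
        spec <- cfg$model
        spec$seed <- fit_seed(cfg, g, q, resp)
        fit <- fit_random_intercept(responses[[resp]]$values,
                                    responses[[resp]]$sites, spec)
        fits[[g]][[paste0("q", q)]][[resp]] <- fit
        mu_row <- fit$summary[fit$summary$parameter == "mu", ]
        summ_rows[[length(summ_rows) + 1L]] <- tibble::tibble(
          group = g, q = q, response = resp,
          mean = mu_row$mean, ci_low = mu_row$ci_low,
          ci_high = mu_row$ci_high, max_rhat = fit$max_rhat,
          converged = fit$converged, n_sites = length(fit$sites))
        if (resp == "delta_beta") {
          sl <- site_level_estimates(fit)
          sl$group <- g
          sl$q <- q
          site_rows[[length(site_rows) + 1L]] <- sl
        }
      }
    }
  }
  deltas <- dplyr::bind_rows(deltas_all)
  posterior_summary <- dplyr::bind_rows(summ_rows)

  # covariates + spatial checks on the community-level richness changes
  covariates <- NULL
  regressions <- NULL
  moran <- NULL
  if ("all" %in% cfg$groups && 0 %in% cfg$q_orders) {
    base <- deltas[deltas$group == "all" & deltas$q == 0, ]
    if (!is.null(site_env)) {
      fg_all <- filter_group(selected, "all")$table
      covariates <- site_covariates(fg_all, site_env, herbivores)
      cov_names <- c("drought_intensity", "grazing_index", "species_pool",
                     "productivity", "mean_block_distance")
      reg_rows <- list()
      for (resp in c("delta_alpha_bar", "delta_gamma", "delta_beta")) {
        y <- base[[resp]][match(covariates$site, base$site)]
        for (cv in cov_names) {
          x <- covariates[[cv]]
          ok <- is.finite(y) & is.finite(x)
          if (sum(ok) >= 3 && stats::var(x[ok]) > 0) {
            r <- covariate_regression(y[ok], x[ok])
            r$response <- resp
            r$covariate <- cv
            reg_rows[[length(reg_rows) + 1L]] <- r
          }
        }
      }
      regressions <- dplyr::bind_rows(reg_rows)
    }
    sm <- attr(table, "site_meta")
    if (!is.null(sm)) {
      coords <- sm[match(base$site, sm$site), ]
      ok <- is.finite(coords$lat) & is.finite(coords$lon)
      if (sum(ok) >= 3) {
        moran <- lapply(
          stats::setNames(c("delta_alpha_bar", "delta_gamma", "delta_beta"),
                          c("delta_alpha_bar", "delta_gamma", "delta_beta")),
          function(resp) {
            morans_i(base[[resp]][ok], coords$lat[ok], coords$lon[ok],
                     n_permutations = cfg$moran_permutations,
                     seed = derive_seed(cfg$seed, 400000L))
          })
      }
    }
  }

  structure(list(deltas = deltas, scenario_counts = counts, fits = fits,
                 posterior_summary = posterior_summary,
                 site_levels = if (length(site_rows))
                   dplyr::bind_rows(site_rows),
                 covariates = covariates,
                 covariate_regressions = regressions, moran = moran,
                 exclusions = exclusions,
                 all_converged = all(posterior_summary$converged),
                 config = cfg),
            class = "result_bundle")
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("<result_bundle> groups: ",
      paste(unique(x$posterior_summary$group), collapse = ", "),
      "; q: ", paste(x$config$q_orders, collapse = ","),
      "; all models converged: ", x$all_converged, "\n", sep = "")
  print(x$posterior_summary[x$posterior_summary$response == "delta_beta", ])
  invisible(x)
}

#' Sensitivity re-analyses: longer duration or more blocks
#'
#' `"year14"` re-runs the analysis at treatment year 14 on the sites that
#' have that snapshot; `"five_blocks"` re-runs with five selected blocks on
#' the sites that have at least five. Everything else is inherited from
#' `cfg`.
#'
#' @param table A [cover_table].
#' @param cfg The main [analysis_config].
#' @param variant `"year14"` or `"five_blocks"`.
#' @param site_env,herbivores Passed through to [run_pipeline()].
#' @return A `result_bundle`.
#' @export
sensitivity_variant <- function(table, cfg = analysis_config(),
                                variant = c("year14", "five_blocks"),
                                site_env = NULL, herbivores = NULL) {
  variant <- match.arg(variant)
  cfg2 <- cfg
  if (variant == "year14") {
    cfg2$year <- 14
    has <- unique(table$site[table$year_trt == 14])
    if (length(has) == 0) {
      abort("no sites have year-14 data",
            class = "divscale_empty_result_error")
    }
  } else {
    cfg2$n_blocks <- 5
    nb <- tapply(table$block, table$site, function(b) length(unique(b)))
    has <- names(nb)[nb >= 5]
    if (length(has) == 0) {
      abort("no sites have five blocks",
            class = "divscale_empty_result_error")
    }
  }
  sub <- table[table$site %in% has, ]
  attr(sub, "site_meta") <- attr(table, "site_meta")
  attr(sub, "block_meta") <- attr(table, "block_meta")
  class(sub) <- class(table)
  run_pipeline(sub, cfg2, site_env = site_env, herbivores = herbivores)
}

#' Write a result bundle to disk
#'
#' Emits the tidy delta table and site-level credible intervals as CSV, and
#' scenario counts, posterior summaries, covariate regressions, Moran
#' results, exclusions and provenance (config hash, seed, package version)
#' as JSON.
#'
#' @param bundle A `result_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  deltas <- bundle$deltas
  deltas$delta_alpha <- vapply(deltas$delta_alpha, paste, "", collapse = ";")
  utils::write.csv(
    deltas[, c("site", "group", "q", "delta_alpha", "delta_alpha_bar",
               "delta_gamma", "delta_beta", "scenario")],
    file.path(dir, "deltas.csv"), row.names = FALSE)
  jsonlite::write_json(bundle$scenario_counts,
                       file.path(dir, "scenario_counts.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(bundle$posterior_summary,
                       file.path(dir, "posterior_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(bundle$site_levels)) {
    utils::write.csv(bundle$site_levels,
                     file.path(dir, "site_level_estimates.csv"),
                     row.names = FALSE)
  }
  if (!is.null(bundle$covariate_regressions)) {
    jsonlite::write_json(bundle$covariate_regressions,
                         file.path(dir, "covariate_regressions.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  if (!is.null(bundle$moran)) {
    moran <- lapply(bundle$moran, function(m) {
      m$permuted <- NULL
      unclass(m)
    })
    jsonlite::write_json(moran, file.path(dir, "moran.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  write_exclusion_report(bundle$exclusions, file.path(dir, "exclusions.json"))
  cfg <- bundle$config
  jsonlite::write_json(
    list(seed = cfg$seed,
         config_hash = rlang::hash(unclass(cfg)),
         package_version = as.character(utils::packageVersion("divscale")),
         r_version = as.character(getRversion())),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
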
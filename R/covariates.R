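#' Drought intensity of a site
#'
#' Mean over the requested years of annual potential evapotranspiration
#' divided by annual precipitation (a unitless aridity ratio; > 1 means
#' evaporative demand exceeds rainfall). By convention the experiment years
#' 0-4 are used.
#'
#' @param annual_pet,annual_precip Equal-length positive numeric vectors
#'   (one value per year, same year order).
#' @return The mean annual PET/precipitation ratio.
#' @export
drought_intensity <- function(annual_pet, annual_precip) {
  stopifnot(length(annual_pet) == length(annual_precip),
            length(annual_pet) >= 1)
  if (any(annual_precip <= 0)) {
    abort("zero or negative annual precipitation: ratio undefined")
  }
  if (any(annual_pet < 0)) abort("negative PET")
  mean(annual_pet / annual_precip)
}

#' Grazing index of a site
#'
#' Sum of per-herbivore importance values, each scored 1 (present, low
#' impact and frequency) to 5 (high impact and frequency) for vertebrate
#' herbivores above 2 kg. An empty list means no large herbivores (index 0).
#'
#' @param importance_values Integer vector with values in 1..5 (possibly
#'   empty).
#' @return The integer index.
#' @export
grazing_index <- function(importance_values) {
  if (length(importance_values) == 0) return(0L)
  if (any(importance_values != round(importance_values)) ||
      any(importance_values < 1) || any(importance_values > 5)) {
    abort("importance values must be integers in 1..5")
  }
  as.integer(sum(importance_values))
}

#' Species pool of a site
#'
#' Total number of distinct taxa recorded in the control plots of the
#' selected blocks over the requested years.
#'
#' @param x A [cover_table] restricted to the selected blocks.
#' @param site Site id.
#' @param years Years (`year_trt`) to pool over (default 0:4).
#' @return Integer species count.
#' @export
species_pool <- function(x, site, years = 0:4) {
  rec <- x[x$site == site & x$trt == "Control" & x$year_trt %in% years, ]
  length(unique(rec$taxon))
}

#' Mean pairwise distance among a site's blocks
#'
#' Great-circle (haversine) distance in meters between each pair of block
#' coordinates, averaged. With three blocks this is the mean of the three
#' pairwise distances. Identical coordinates give 0 and are flagged as
#' degenerate with a message.
#'
#' @param block_lat,block_lon Numeric vectors of block coordinates
#'   (degrees), one per selected block.
#' @return Mean pairwise distance in meters.
#' @export
mean_block_distance <- function(block_lat, block_lon) {
  stopifnot(length(block_lat) == length(block_lon), length(block_lat) >= 2)
  if (anyNA(block_lat) || anyNA(block_lon)) {
    abort("missing block coordinates", class = "divscale_missing_coords_error")
  }
  pairs <- utils::combn(length(block_lat), 2)
  d <- apply(pairs, 2, function(p) {
    geosphere::distHaversine(c(block_lon[p[1]], block_lat[p[1]]),
                             c(block_lon[p[2]], block_lat[p[2]]))
  })
  m <- mean(d)
  if (m == 0) inform("mean_block_distance: identical coordinates (degenerate)")
  m
}

#' Ordinary least-squares regression of diversity change on a covariate
#'
#' One response, one predictor, fitted by [stats::lm()]; reports the slope,
#' intercept, the slope's standard error and two-sided t-test p-value, and
#' r-squared.
#'
#' @param delta Per-site response values.
#' @param covariate Per-site predictor values (same length, >= 3 pairs).
#' @return A one-row tibble: `slope`, `intercept`, `se`, `p_value`,
#'   `r_squared`, `n`.
#' @export
covariate_regression <- function(delta, covariate) {
  stopifnot(length(delta) == length(covariate))
  ok <- is.finite(delta) & is.finite(covariate)
  delta <- delta[ok]
  covariate <- covariate[ok]
  if (length(delta) < 3) abort("need at least 3 complete pairs")
  if (stats::var(covariate) == 0) {
    abort("covariate has zero variance", class = "divscale_degenerate_error")
  }
  fit <- stats::lm(delta ~ covariate)
  cf <- summary(fit)$coefficients
  tibble::tibble(slope = cf["covariate", "Estimate"],
                 intercept = cf["(Intercept)", "Estimate"],
                 se = cf["covariate", "Std. Error"],
                 p_value = cf["covariate", "Pr(>|t|)"],
                 r_squared = summary(fit)$r.squared,
                 n = length(delta))
}

# Row-standardized inverse-haversine-distance weights, zero diagonal.
inverse_distance_weights <- function(lat, lon) {
  n <- length(lat)
  d <- geosphere::distm(cbind(lon, lat), fun = geosphere::distHaversine)
  w <- 1 / d
  diag(w) <- 0
  w[!is.finite(w)] <- 0   # coincident sites contribute no weight
  rs <- rowSums(w)
  rs[rs == 0] <- 1
  w / rs
}

#' Moran's I spatial autocorrelation with a permutation test
#'
#' Computes `I = (n/W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) /
#' sum_i (x_i - xbar)^2` with row-standardized inverse great-circle-distance
#' weights (`w_ii = 0`), its expectation under no autocorrelation
#' `E[I] = -1/(n-1)`, and a permutation p-value obtained by relabelling the
#' values over the fixed coordinates.
#'
#' @param values Per-site values (length n >= 3).
#' @param lat,lon Per-site coordinates in degrees.
#' @param n_permutations Number of random relabelings (default 999).
#' @param seed Integer seed for the permutations.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return A `moran_result` list: `observed`, `expected`, `p_value`, `n`,
#'   `n_permutations`, `alternative`, `weights` (`"inverse_haversine_row_std"`),
#'   `permuted` (the permutation draws of I).
#' @export
morans_i <- function(values, lat, lon, n_permutations = 999, seed = 1,
                     alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n <- length(values)
  stopifnot(n >= 3, length(lat) == n, length(lon) == n)
  if (stats::var(values) == 0) {
    abort("Moran's I undefined for constant values (degenerate)",
          class = "divscale_degenerate_error")
  }
  w <- inverse_distance_weights(lat, lon)
  moran_stat <- function(x) {
    z <- x - mean(x)
    (n / sum(w)) * as.numeric(t(z) %*% w %*% z) / sum(z^2)
  }
  obs <- moran_stat(values)
  expected <- -1 / (n - 1)
  set.seed(seed)
  perm <- vapply(seq_len(n_permutations),
                 function(i) moran_stat(sample(values)), numeric(1))
  p <- switch(alternative,
    greater = (1 + sum(perm >= obs)) / (n_permutations + 1),
    less = (1 + sum(perm <= obs)) / (n_permutations + 1),
    two.sided = {
      dev <- abs(perm - expected)
      (1 + sum(dev >= abs(obs - expected))) / (n_permutations + 1)
    })
  structure(list(observed = obs, expected = expected, p_value = p, n = n,
                 n_permutations = n_permutations, alternative = alternative,
                 weights = "inverse_haversine_row_std", permuted = perm),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat("Moran's I = ", format(x$observed, digits = 4),
      " (expected ", format(x$expected, digits = 4), " under no autocorrelation), ",
      "permutation p = ", format(x$p_value, digits = 3),
      " [", x$alternative, ", ", x$n_permutations, " permutations, n = ",
      x$n, "]\n", sep = "")
  invisible(x)
}

#' Assemble the site-covariate table of a study
#'
#' Builds, per site: drought intensity (years 0-4), grazing index, species
#' pool (control plots, selected blocks, years 0-4), productivity (mean
#' control aboveground biomass years 0-4, scaled from the 0.2 m^2 harvest to
#' g m^-2), and mean block distance (NA when block coordinates are missing;
#' such sites are simply omitted from distance regressions).
#'
#' @param x A [cover_table] restricted to the selected blocks.
#' @param site_env A data frame with one row per site x year: columns
#'   `site`, `year`, `pet`, `precip`, `biomass_g_per_0.2m2` (control
#'   biomass harvest, 0.2 m^2 strips).
#' @param herbivores A data frame with columns `site`, `importance` (one row
#'   per herbivore species; sites absent have no large herbivores).
#' @param years Years used for the temporal averages (default 0:4).
#' @param biomass_scale Multiplier from the harvest area to 1 m^2
#'   (default 5, i.e. 0.2 m^2 -> g m^-2).
#' @return A `site_covariates` tibble: `site`, `drought_intensity`,
#'   `grazing_index`, `species_pool`, `productivity`,
#'   `mean_block_distance`.
#' @export
site_covariates <- function(x, site_env, herbivores = NULL, years = 0:4,
                            biomass_scale = 5) {
  bm <- attr(x, "block_meta")
  rows <- lapply(unique(x$site), function(s) {
    env <- site_env[site_env$site == s & site_env$year %in% years, ]
    di <- if (nrow(env) > 0) drought_intensity(env$pet, env$precip) else NA_real_
    prod <- if (nrow(env) > 0) {
      mean(env$biomass_g_per_0.2m2) * biomass_scale
    } else NA_real_
    gi <- if (!is.null(herbivores)) {
      grazing_index(herbivores$importance[herbivores$site == s])
    } else 0L
    mbd <- NA_real_
    if (!is.null(bm)) {
      b <- bm[bm$site == s & bm$block %in% unique(x$block[x$site == s]), ]
      if (nrow(b) >= 2 && !anyNA(b$block_lat) && !anyNA(b$block_lon)) {
        mbd <- mean_block_distance(b$block_lat, b$block_lon)
      }
    }
    tibble::tibble(site = s, drought_intensity = di, grazing_index = gi,
                   species_pool = species_pool(x, s, years),
                   productivity = prod, mean_block_distance = mbd)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("site_covariates", class(out))
  out
}
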
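#' Log response ratios of diversity across scales for one site
#'
#' Natural-log response ratios of nutrient addition relative to control:
#' per-block `delta_alpha = ln(alpha_NPK / alpha_Control)` (paired within
#' block), their arithmetic mean `delta_alpha_bar`,
#' `delta_gamma = ln(gamma_NPK / gamma_Control)`, and
#' `delta_beta = delta_gamma - delta_alpha_bar`. A negative `delta_beta`
#' means nutrient addition made the subplots more similar to each other
#' (biotic homogenization); positive means differentiation. `delta_beta`
#' equals `ln(beta_geom_NPK) - ln(beta_geom_Control)` identically.
#'
#' @param npk,control Rows of a [scale_diversity] table for one site: the
#'   NPK and Control slices, with matching blocks and order `q`.
#' @return A one-row tibble of class `delta_diversity` with columns `site`,
#'   `q`, `delta_alpha` (list column of per-block log ratios),
#'   `delta_alpha_bar`, `delta_gamma`, `delta_beta`, `scenario`.
#' @export
compute_deltas <- function(npk, control) {
  stopifnot(nrow(npk) >= 1, nrow(control) >= 1)
  if (length(unique(c(npk$site, control$site))) != 1) {
    abort("compute_deltas expects both slices to come from one site")
  }
  if (length(unique(c(npk$q, control$q))) != 1) {
    abort("diversity order q differs between slices")
  }
  npk <- npk[order(match(npk$block, block_order(npk$block))), ]
  control <- control[order(match(control$block, block_order(control$block))), ]
  if (!identical(npk$block, control$block)) {
    abort("NPK and Control slices must cover the same blocks")
  }
  if (any(npk$alpha <= 0) || any(control$alpha <= 0) ||
      npk$gamma[1] <= 0 || control$gamma[1] <= 0) {
    abort("zero diversity encountered: log response ratio undefined (site should have been excluded by filter_group)",
          class = "divscale_undefined_log_error")
  }
  d_alpha <- log(npk$alpha / control$alpha)
  d_alpha_bar <- mean(d_alpha)
  d_gamma <- log(npk$gamma[1] / control$gamma[1])
  d_beta <- d_gamma - d_alpha_bar
  out <- tibble::tibble(
    site = npk$site[1], q = npk$q[1],
    delta_alpha = list(stats::setNames(d_alpha, npk$block)),
    delta_alpha_bar = d_alpha_bar,
    delta_gamma = d_gamma,
    delta_beta = d_beta,
    scenario = classify_scenario(d_alpha_bar, d_gamma))
  class(out) <- c("delta_diversity", class(out))
  out
}

#' Delta table for every site of a scale-diversity table
#'
#' @param div A [scale_diversity] tibble (both treatments, all sites).
#' @return A `delta_diversity` tibble, one row per site.
#' @export
delta_table <- function(div) {
  rows <- lapply(unique(div$site), function(s) {
    compute_deltas(div[div$site == s & div$trt == "NPK", ],
                   div[div$site == s & div$trt == "Control", ])
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("delta_diversity", class(out))
  out
}

#' Classify a site into the six homogenization/differentiation scenarios
#'
#' Homogenization (`delta_gamma < delta_alpha_bar`, i.e. `delta_beta < 0`):
#' scenario I when both ratios are positive, II when
#' `delta_gamma < 0 < delta_alpha_bar` (spatially restricted species replaced
#' by widespread ones), III when both are negative. Differentiation
#' (`delta_beta > 0`): IV when both negative, V when
#' `delta_alpha_bar < 0 < delta_gamma`, VI when both positive. A site with
#' `delta_alpha_bar = 0`, `delta_gamma = 0` or `delta_beta = 0` (on the 1:1
#' diagonal) belongs to no scenario and is labelled `"uncounted"`. Zero
#' comparisons are exact: richness ratios are ratios of small integers, so no
#' tolerance band is applied.
#'
#' @param delta_alpha_bar,delta_gamma Finite log response ratios.
#' @return One of `"I" ... "VI"` or `"uncounted"`.
#' @export
classify_scenario <- function(delta_alpha_bar, delta_gamma) {
  if (!is_number(delta_alpha_bar) || !is_number(delta_gamma)) {
    abort("classify_scenario requires finite inputs")
  }
  da <- delta_alpha_bar
  dg <- delta_gamma
  db <- dg - da
  if (da == 0 || dg == 0 || db == 0) return("uncounted")
  if (db < 0) {               # homogenization
    if (da > 0 && dg > 0) "I"
    else if (dg < 0 && da > 0) "II"
    else "III"                # both < 0 (da < 0 implies dg < 0 here)
  } else {                    # differentiation
    if (da < 0 && dg < 0) "IV"
    else if (da < 0 && dg > 0) "V"
    else "VI"                 # both > 0
  }
}

#' Count sites per scenario and per direction of beta change
#'
#' @param deltas A `delta_diversity` tibble with one row per site.
#' @return A list with `scenario` (named integer vector over I..VI and
#'   uncounted), `homogenization` (sites with raw `delta_beta < 0`),
#'   `differentiation` (`delta_beta > 0`), `no_change` (`delta_beta == 0`),
#'   and `n_sites`.
#' @export
scenario_counts <- function(deltas) {
  if (anyDuplicated(deltas$site)) {
    abort("scenario_counts expects one row per site")
  }
  levs <- c("I", "II", "III", "IV", "V", "VI", "uncounted")
  sc <- table(factor(deltas$scenario, levels = levs))
  list(scenario = stats::setNames(as.integer(sc), levs),
       homogenization = sum(deltas$delta_beta < 0),
       differentiation = sum(deltas$delta_beta > 0),
       no_change = sum(deltas$delta_beta == 0),
       n_sites = nrow(deltas))
}
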
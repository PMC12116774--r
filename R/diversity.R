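#' Hill-number diversity of one assemblage
#'
#' Effective number of species of order `q` for a vector of positive cover
#' values: `D_q = (sum p_i^q)^(1/(1-q))` with `p_i = cover_i / sum(cover)`.
#' `q = 0` is species richness, `q = 1` the exponential of Shannon entropy
#' (computed by its analytic limit), `q = 2` inverse Simpson concentration.
#' Increasing `q` down-weights rare species. The result always lies in
#' `[1, S]` and is invariant to rescaling all covers by a constant.
#'
#' @param covers Numeric vector of positive covers (one per species).
#' @param q Diversity order, a single number >= 0.
#' @return The effective number of species.
#' @export
hill_number <- function(covers, q) {
  if (length(covers) == 0) {
    abort("diversity of an empty assemblage is undefined",
          class = "divscale_empty_assemblage_error")
  }
  if (any(!is.finite(covers)) || any(covers <= 0)) {
    abort("covers must be finite and strictly positive")
  }
  stopifnot(is_number(q), q >= 0)
  p <- covers / sum(covers)
  if (q == 0) {
    length(p)
  } else if (abs(q - 1) < 1e-10) {
    exp(-sum(p * log(p)))
  } else {
    sum(p^q)^(1 / (1 - q))
  }
}

# Internal: records for one site/treatment/year restricted to given blocks.
subplot_covers <- function(x, site, treatment, year) {
  x[x$site == site & x$trt == treatment & x$year_trt == year, ]
}

#' Subplot-scale (alpha) diversity, one value per block
#'
#' Computes the Hill number of each 1 m x 1 m subplot of a treatment at a
#' site. Blocks are returned in their field order (numeric when block labels
#' are numbers).
#'
#' @param x A [cover_table] already restricted to the selected blocks.
#' @param site,treatment,year Which subplots to use.
#' @param q Diversity order.
#' @return A named numeric vector, one alpha value per block.
#' @export
alpha_diversity <- function(x, site, treatment, year, q) {
  rec <- subplot_covers(x, site, treatment, year)
  blocks <- block_order(x$block[x$site == site])
  if (length(blocks) == 0 || nrow(rec) == 0) {
    abort(paste0("no records for site ", site, ", treatment ", treatment,
                 ", year ", year),
          class = "divscale_structure_error")
  }
  missing <- setdiff(blocks, unique(rec$block))
  if (length(missing) > 0) {
    abort(paste0("site ", site, " block(s) ",
                 paste(missing, collapse = ", "),
                 " lack the ", treatment, " subplot in year ", year),
          class = "divscale_structure_error")
  }
  stats::setNames(
    vapply(blocks, function(b) hill_number(rec$cover[rec$block == b], q),
           numeric(1)),
    as.character(blocks))
}

#' Pooled-scale (gamma) diversity of one treatment at a site
#'
#' For `q = 0`, the size of the union of species across the treatment's
#' selected subplots. For `q > 0`, the Hill number of the pooled assemblage:
#' per-species covers are summed across subplots and renormalized — the
#' standard pooling convention of the multiplicative diversity partition.
#'
#' @inheritParams alpha_diversity
#' @return The pooled effective number of species.
#' @export
gamma_diversity <- function(x, site, treatment, year, q) {
  rec <- subplot_covers(x, site, treatment, year)
  if (nrow(rec) == 0) {
    abort(paste0("no records for site ", site, ", treatment ", treatment,
                 ", year ", year),
          class = "divscale_structure_error")
  }
  pooled <- tapply(rec$cover, rec$taxon, sum)
  hill_number(as.numeric(pooled), q)
}

#' Beta diversity as an effective number of communities
#'
#' Whittaker's multiplicative partition: gamma divided by a mean of the
#' per-subplot alphas. With the arithmetic mean the result for richness
#' (q = 0) is bounded by `[1, n_blocks]`: 1 when all subplots share the same
#' species, `n_blocks` when every subplot is unique. The geometric-mean
#' variant is the one whose logarithm the log-response-ratio partition
#' decomposes exactly.
#'
#' @param alpha_by_block Numeric vector of per-block alpha values (> 0).
#' @param gamma Pooled diversity.
#' @param mean_kind `"arithmetic"` or `"geometric"`.
#' @param strict Require `gamma >= max(alpha)` (default TRUE). This holds
#'   identically for richness, where the pooled species set contains every
#'   subplot's, so a violation signals inconsistent inputs; for orders
#'   q > 0 with summed-cover pooling the pooled effective number can
#'   legitimately fall below a subplot's, and callers disable the check.
#' @return The effective number of communities.
#' @export
beta_effective <- function(alpha_by_block, gamma,
                           mean_kind = c("arithmetic", "geometric"),
                           strict = TRUE) {
  mean_kind <- match.arg(mean_kind)
  stopifnot(length(alpha_by_block) >= 1, all(alpha_by_block > 0),
            is_number(gamma))
  if (strict && gamma < max(alpha_by_block) - 1e-9) {
    abort("gamma must be at least max(alpha): pooled diversity contains every subplot's species",
          class = "divscale_inconsistency_error")
  }
  m <- switch(mean_kind,
              arithmetic = mean(alpha_by_block),
              geometric = exp(mean(log(alpha_by_block))))
  gamma / m
}

#' Alpha, gamma and beta diversity for every site x treatment
#'
#' Convenience wrapper assembling the full scale decomposition for each site
#' and treatment at one analysis year and diversity order.
#'
#' @param x A [cover_table] already restricted to the selected blocks.
#' @param year Analysis year (`year_trt`).
#' @param q Diversity order.
#' @return A tibble of class `scale_diversity` with one row per
#'   site x treatment x block carrying `alpha`, and the site-level `gamma`,
#'   `beta_arith` and `beta_geom` repeated across blocks.
#' @export
scale_diversity <- function(x, year, q) {
  rows <- list()
  for (s in unique(x$site)) {
    for (tr in TREATMENTS) {
      a <- alpha_diversity(x, s, tr, year, q)
      g <- gamma_diversity(x, s, tr, year, q)
      ba <- beta_effective(a, g, "arithmetic", strict = (q == 0))
      bg <- beta_effective(a, g, "geometric", strict = (q == 0))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        site = s, trt = tr, q = q,
        block = names(a), alpha = unname(a), gamma = g,
        beta_arith = ba, beta_geom = bg)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("scale_diversity", class(out))
  out
}
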
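# Fixture builders: tiny cover tables assembled in code.

# One record row.
rec <- function(site, block, trt, taxon, cover = 10, year = 4,
                is_native = "native", lifeform = "forb") {
  tibble::tibble(site = site, block = block, trt = trt, year_trt = year,
                 taxon = taxon, cover = cover, is_native = is_native,
                 lifeform = lifeform)
}

# Build a one-site cover_table from per-block species sets:
# sets = list(Control = list(`1` = c("a","b"), ...), NPK = list(...)).
# Covers default to 10 for every species.
ct_from_sets <- function(sets, site = "s1", year = 4, covers = NULL) {
  rows <- list()
  for (trt in names(sets)) {
    for (b in names(sets[[trt]])) {
      taxa <- sets[[trt]][[b]]
      cv <- if (is.null(covers)) rep(10, length(taxa)) else
        covers[[trt]][[b]]
      rows[[length(rows) + 1L]] <-
        rec(site, as.integer(b), trt, taxa, cv, year)
    }
  }
  cover_table(dplyr::bind_rows(rows))
}

# The documented six-row toy: 1 site, 3 blocks x 2 treatments, 1 taxon each.
toy_six_rows <- function() {
  dplyr::bind_rows(lapply(1:3, function(b) {
    dplyr::bind_rows(rec("s1", b, "Control", "sp_a"),
                     rec("s1", b, "NPK", "sp_b"))
  }))
}

write_toy_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Independently coded scenario truth table, written straight from the
# framework's per-scenario inequality definitions (each scenario tested
# separately; exactly one may match).
scenario_oracle <- function(da, dg) {
  db <- dg - da
  if (da == 0 || dg == 0 || db == 0) return("uncounted")
  defs <- list(
    I = (dg < da) && (dg > 0) && (da > 0),
    II = (dg < da) && (dg < 0) && (da > 0),
    III = (dg < da) && (dg < 0) && (da < 0),
    IV = (dg > da) && (dg < 0) && (da < 0),
    V = (dg > da) && (dg > 0) && (da < 0),
    VI = (dg > da) && (dg > 0) && (da > 0))
  hit <- names(defs)[vapply(defs, isTRUE, logical(1))]
  stopifnot(length(hit) == 1)
  hit
}

# A quick random one-site scale_diversity pair for partition identity tests:
# returns list(npk, control) slices built from random assemblages.
random_site_diversity <- function(q, n_blocks = 3, pool = 30) {
  species <- sprintf("sp%02d", seq_len(pool))
  slice <- function(trt) {
    alphas <- numeric(n_blocks)
    pooled <- list()
    for (b in seq_len(n_blocks)) {
      taxa <- sample(species, sample(3:15, 1))
      cv <- stats::setNames(stats::rlnorm(length(taxa), 1.5, 1), taxa)
      alphas[b] <- hill_number(unname(cv), q)
      pooled[[b]] <- cv
    }
    all_cv <- unlist(pooled)
    gamma <- hill_number(as.numeric(tapply(all_cv, names(all_cv), sum)), q)
    a <- alphas
    ba <- beta_effective(a, gamma, "arithmetic", strict = (q == 0))
    bg <- beta_effective(a, gamma, "geometric", strict = (q == 0))
    tibble::tibble(site = "s1", trt = trt, q = q,
                   block = as.character(seq_len(n_blocks)), alpha = a,
                   gamma = gamma, beta_arith = ba, beta_geom = bg)
  }
  list(npk = slice("NPK"), control = slice("Control"))
}
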
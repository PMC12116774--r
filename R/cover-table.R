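#' Long-format species-cover tables
#'
#' A `cover_table` holds visually estimated percent-cover observations from a
#' blocked, paired-plot experiment: one row per species record in one 1 m x
#' 1 m subplot (site x block x treatment x treatment-year). Absence is
#' encoded by absence of a row, so every stored cover is strictly positive;
#' per-subplot total cover may exceed 100% (multilayer canopies) and is never
#' rejected. Optional site metadata (coordinates, per-block coordinates) ride
#' along as attributes.
#'
#' @param records A data frame with columns `site`, `block`, `trt`
#'   (`"Control"` or `"NPK"`), `year_trt` (integer years since treatments
#'   began, 0 = pre-treatment), `taxon`, `cover` (percent, > 0), `is_native`
#'   (`"native"`, `"non-native"` or `"unknown"`), `lifeform` (`"forb"`,
#'   `"graminoid"`, `"legume"`, `"woody"` or `"unknown"`).
#' @param site_meta Optional data frame with columns `site`, `lat`, `lon`.
#' @param block_meta Optional data frame with columns `site`, `block`,
#'   `block_lat`, `block_lon`.
#'
#' @return A tibble of class `cover_table` with `site_meta` and `block_meta`
#'   attributes.
#' @export
cover_table <- function(records, site_meta = NULL, block_meta = NULL) {
  required <- c("site", "block", "trt", "year_trt", "taxon", "cover",
                "is_native", "lifeform")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("cover table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "divscale_schema_error")
  }
  records <- tibble::as_tibble(records)[required]
  if (!is.numeric(records$cover)) {
    bad <- which(is.na(suppressWarnings(as.numeric(records$cover))))
    abort(paste0("non-numeric cover value(s), first at row ",
                 if (length(bad)) bad[1] else NA),
          class = "divscale_parse_error")
  }
  if (anyNA(records$cover)) {
    abort(paste0("missing cover value, first at row ",
                 which(is.na(records$cover))[1]),
          class = "divscale_parse_error")
  }
  records$cover <- as.double(records$cover)
  bad_trt <- setdiff(unique(records$trt), TREATMENTS)
  if (length(bad_trt) > 0) {
    abort(paste0("unknown treatment label(s): ",
                 paste(bad_trt, collapse = ", ")),
          class = "divscale_schema_error")
  }
  bad_nat <- setdiff(unique(records$is_native),
                     c("native", "non-native", "unknown"))
  if (length(bad_nat) > 0) {
    abort(paste0("unknown is_native label(s): ",
                 paste(bad_nat, collapse = ", ")),
          class = "divscale_schema_error")
  }
  bad_lf <- setdiff(unique(records$lifeform),
                    c("forb", "graminoid", "legume", "woody", "unknown"))
  if (length(bad_lf) > 0) {
    abort(paste0("unknown lifeform label(s): ",
                 paste(bad_lf, collapse = ", ")),
          class = "divscale_schema_error")
  }

  n_dropped <- sum(records$cover <= 0)
  if (n_dropped > 0) {
    warn(paste0("dropped ", n_dropped,
                " record(s) with cover <= 0 (absence is encoded by absence)"))
    records <- records[records$cover > 0, ]
  }

  key <- paste(records$site, records$block, records$trt, records$year_trt,
               records$taxon, sep = "\r")
  if (anyDuplicated(key)) {
    first_dup <- key[duplicated(key)][1]
    abort(paste0("duplicate (site, block, trt, year_trt, taxon) key: (",
                 gsub("\r", ", ", first_dup, fixed = TRUE), ")"),
          class = "divscale_duplicate_key_error")
  }

  structure(records,
            site_meta = if (!is.null(site_meta)) tibble::as_tibble(site_meta),
            block_meta = if (!is.null(block_meta)) tibble::as_tibble(block_meta),
            class = c("cover_table", class(records)))
}

#' @export
print.cover_table <- function(x, ...) {
  cat("<cover_table> ", nrow(x), " records, ",
      length(unique(x$site)), " site(s), years ",
      paste(sort(unique(x$year_trt)), collapse = "/"), "\n", sep = "")
  NextMethod()
}

#' Read a species-cover CSV
#'
#' Reads the documented long-format CSV dialect (UTF-8, header row, columns
#' `site,block,trt,year_trt,taxon,cover,is_native,lifeform`) and, optionally,
#' a site-metadata CSV (`site,lat,lon` with optional
#' `block,block_lat,block_lon` rows). Rows with `cover <= 0` are dropped with
#' a warning; duplicated record keys are an error.
#'
#' @param path Path to the cover CSV.
#' @param site_meta_path Optional path to the site-metadata CSV.
#' @return A [cover_table].
#' @export
read_cover_table <- function(path, site_meta_path = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8")
  site_meta <- NULL
  block_meta <- NULL
  if (!is.null(site_meta_path)) {
    meta <- utils::read.csv(site_meta_path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
    if (!all(c("site", "lat", "lon") %in% names(meta))) {
      abort("site metadata must have columns site, lat, lon",
            class = "divscale_schema_error")
    }
    if (all(c("block", "block_lat", "block_lon") %in% names(meta))) {
      block_meta <- tibble::as_tibble(
        meta[!is.na(meta$block), c("site", "block", "block_lat", "block_lon")])
    }
    site_meta <- tibble::as_tibble(unique(meta[c("site", "lat", "lon")]))
    site_meta <- site_meta[stats::complete.cases(site_meta), ]
  }
  cover_table(records, site_meta = site_meta, block_meta = block_meta)
}

#' Write a cover table back to the CSV dialect
#'
#' @param x A [cover_table].
#' @param path Output CSV path.
#' @param site_meta_path Optional output path for site/block metadata.
#' @return `path`, invisibly.
#' @export
write_cover_table <- function(x, path, site_meta_path = NULL) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  if (!is.null(site_meta_path)) {
    sm <- attr(x, "site_meta")
    bm <- attr(x, "block_meta")
    if (!is.null(sm)) {
      out <- as.data.frame(sm)
      out$block <- NA
      out$block_lat <- NA
      out$block_lon <- NA
      if (!is.null(bm)) {
        bm2 <- merge(as.data.frame(bm), as.data.frame(sm), by = "site")
        out <- rbind(out,
                     bm2[, c("site", "lat", "lon", "block", "block_lat",
                             "block_lon")])
      }
      utils::write.csv(out, site_meta_path, row.names = FALSE,
                       fileEncoding = "UTF-8")
    }
  }
  invisible(path)
}

# Order block labels the way field crews number them: numerically when every
# label parses as a number, lexicographically otherwise; ties keep first
# appearance.
block_order <- function(blocks) {
  u <- unique(blocks)
  num <- suppressWarnings(as.numeric(u))
  if (!anyNA(num)) u[order(num)] else u[order(u)]
}

#' Standardize sampling effort by selecting the first blocks of each site
#'
#' Retains, per site, the `n_blocks` lowest-numbered blocks (ascending by
#' block label, numeric when possible), mirroring the convention of using the
#' first blocks recorded by site PIs. Sites with fewer than `n_blocks` blocks
#' are dropped and reported in the `dropped_sites` attribute.
#'
#' @param x A [cover_table].
#' @param n_blocks Number of blocks to keep per site (>= 2; default 3).
#' @return A [cover_table] with at most `n_blocks` blocks per site and a
#'   `dropped_sites` character-vector attribute.
#' @export
select_blocks <- function(x, n_blocks = 3) {
  stopifnot(inherits(x, "cover_table"), n_blocks >= 2)
  keep <- logical(nrow(x))
  dropped <- character(0)
  for (s in unique(x$site)) {
    idx <- x$site == s
    ord <- block_order(x$block[idx])
    if (length(ord) < n_blocks) {
      dropped <- c(dropped, s)
      next
    }
    keep[idx] <- x$block[idx] %in% ord[seq_len(n_blocks)]
  }
  if (length(dropped) > 0) {
    inform(paste0("select_blocks: dropped ", length(dropped),
                  " site(s) with fewer than ", n_blocks, " blocks: ",
                  paste(dropped, collapse = ", ")))
  }
  out <- x[keep, ]
  attr(out, "site_meta") <- attr(x, "site_meta")
  attr(out, "block_meta") <- attr(x, "block_meta")
  attr(out, "dropped_sites") <- dropped
  class(out) <- class(x)
  out
}

#' Species-group specifications
#'
#' Builds a predicate over `(is_native, lifeform)` selecting one of the
#' standard analysis groups: the entire community (`"all"`), the
#' native/non-native pair, or one of the four lifeforms. Records with
#' `"unknown"` status never match a specific group but are always part of
#' `"all"`.
#'
#' @param name One of `"all"`, `"native"`, `"non-native"`, `"forb"`,
#'   `"graminoid"`, `"legume"`, `"woody"`.
#' @return A `group_spec` list with fields `name` and `predicate`.
#' @export
group_spec <- function(name) {
  predicate <- switch(
    name,
    all          = function(is_native, lifeform) rep(TRUE, length(is_native)),
    native       = function(is_native, lifeform) is_native == "native",
    `non-native` = function(is_native, lifeform) is_native == "non-native",
    forb         = function(is_native, lifeform) lifeform == "forb",
    graminoid    = function(is_native, lifeform) lifeform == "graminoid",
    legume       = function(is_native, lifeform) lifeform == "legume",
    woody        = function(is_native, lifeform) lifeform == "woody",
    abort(paste0("unknown group name: ", name))
  )
  structure(list(name = name, predicate = predicate), class = "group_spec")
}

#' Restrict a cover table to one species group
#'
#' Removes records outside the group, then excludes every site where any
#' analysis subplot (either treatment, any selected block) holds zero
#' matching species: the downstream log response ratio of a zero richness is
#' undefined (log(0)), so such sites cannot enter the group's analysis.
#'
#' @param x A [cover_table], already restricted to the selected blocks and
#'   analysis year.
#' @param group A [group_spec] or a group name.
#' @return A list with elements `table` (the filtered [cover_table]) and
#'   `excluded_sites` (character vector).
#' @export
filter_group <- function(x, group) {
  if (is.character(group)) group <- group_spec(group)
  stopifnot(inherits(x, "cover_table"), inherits(group, "group_spec"))
  match_idx <- group$predicate(x$is_native, x$lifeform)

  # every analysis subplot (each block x both treatments, per year the site
  # was sampled) must keep >= 1 matching species; a subplot with no rows at
  # all counts as empty too
  sby <- unique(tibble::tibble(site = x$site, block = x$block,
                               year_trt = x$year_trt))
  expected <- tidyr::crossing(sby, trt = TREATMENTS)
  expected_key <- paste(expected$site, expected$block, expected$trt,
                        expected$year_trt, sep = "\r")
  subplot <- paste(x$site, x$block, x$trt, x$year_trt, sep = "\r")
  ok_subplots <- unique(subplot[match_idx])
  empty <- setdiff(expected_key, ok_subplots)
  excluded <- unique(vapply(strsplit(empty, "\r", fixed = TRUE), `[[`, "", 1L))

  keep <- match_idx & !(x$site %in% excluded)
  out <- x[keep, ]
  attr(out, "site_meta") <- attr(x, "site_meta")
  attr(out, "block_meta") <- attr(x, "block_meta")
  class(out) <- class(x)
  if (length(excluded) > 0) {
    inform(paste0("filter_group(", group$name, "): excluded ",
                  length(excluded), " site(s) with an empty subplot: ",
                  paste(sort(excluded), collapse = ", ")))
  }
  list(table = out, excluded_sites = sort(excluded))
}

#' Collapse repeat surveys within a year to the maximum cover per species
#'
#' Sites surveyed more than once per year keep, for each species in each
#' subplot, the maximum recorded cover. A no-op for already-collapsed tables.
#'
#' @param records A data frame in the cover-table column layout (may contain
#'   duplicated record keys, which is what this helper resolves).
#' @return A tibble with unique record keys.
#' @export
collapse_max_cover <- function(records) {
  records |>
    dplyr::group_by(.data$site, .data$block, .data$trt, .data$year_trt,
                    .data$taxon) |>
    dplyr::summarise(
      cover = max(.data$cover),
      is_native = .data$is_native[1],
      lifeform = .data$lifeform[1],
      .groups = "drop") |>
    dplyr::select("site", "block", "trt", "year_trt", "taxon", "cover",
                  "is_native", "lifeform")
}

#' Write a site-exclusion report as JSON
#'
#' @param exclusions A named list mapping a reason (e.g. group name,
#'   `"too_few_blocks"`) to a character vector of excluded site ids.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(exclusions, path) {
  jsonlite::write_json(exclusions, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
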
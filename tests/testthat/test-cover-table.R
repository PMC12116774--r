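test_that("reading the documented CSV dialect preserves rows and types", {
  path <- write_toy_csv(toy_six_rows())
  tab <- read_cover_table(path)
  expect_s3_class(tab, "cover_table")
  expect_equal(nrow(tab), 6)
  expect_type(tab$cover, "double")
  expect_setequal(unique(tab$trt), c("Control", "NPK"))
})

test_that("zero-cover rows are dropped with a warning (absence encoding)", {
  df <- dplyr::bind_rows(toy_six_rows(), rec("s1", 1, "Control", "zero", 0))
  path <- write_toy_csv(df)
  expect_warning(tab <- read_cover_table(path), "cover <= 0")
  expect_equal(nrow(tab), 6)
  expect_false("zero" %in% tab$taxon)
})

test_that("schema violations raise informative errors", {
  dup <- dplyr::bind_rows(toy_six_rows(), rec("s1", 1, "Control", "sp_a"))
  expect_error(read_cover_table(write_toy_csv(dup)),
               class = "divscale_duplicate_key_error")
  expect_error(read_cover_table(write_toy_csv(dup)), "sp_a")

  missing_col <- toy_six_rows()[, -6]
  expect_error(read_cover_table(write_toy_csv(missing_col)),
               class = "divscale_schema_error")

  bad_cover <- toy_six_rows()
  bad_cover$cover <- as.character(bad_cover$cover)
  bad_cover$cover[3] <- "lots"
  expect_error(read_cover_table(write_toy_csv(bad_cover)),
               class = "divscale_parse_error")

  expect_error(read_cover_table(tempfile()), "not found")
})

test_that("per-subplot total cover above 100% is accepted", {
  df <- rec("s1", 1, "Control", c("a", "b", "c"), c(80, 70, 60))
  expect_silent(tab <- cover_table(df))
  expect_equal(sum(tab$cover), 210)
})

test_that("a written table reads back identically up to row order", {
  tab <- ct_from_sets(list(
    Control = list(`1` = c("a", "b"), `2` = c("b", "c"), `3` = c("c")),
    NPK = list(`1` = c("a"), `2` = c("c", "d"), `3` = c("d"))))
  path <- tempfile(fileext = ".csv")
  write_cover_table(tab, path)
  back <- read_cover_table(path)
  key <- function(x) do.call(order, as.list(x[c("site", "block", "trt",
                                                "year_trt", "taxon")]))
  expect_equal(as.data.frame(back[key(back), ]),
               as.data.frame(tab[key(tab), ]),
               ignore_attr = TRUE)
})

test_that("site and block metadata round-trip through the metadata CSV", {
  tab <- cover_table(toy_six_rows(),
                     site_meta = tibble::tibble(site = "s1", lat = 45.5,
                                                lon = -93.2),
                     block_meta = tibble::tibble(site = "s1", block = 1:3,
                                                 block_lat = 45.5 + 1:3 * 1e-4,
                                                 block_lon = -93.2))
  p1 <- tempfile(fileext = ".csv")
  p2 <- tempfile(fileext = ".csv")
  write_cover_table(tab, p1, site_meta_path = p2)
  back <- read_cover_table(p1, site_meta_path = p2)
  expect_equal(attr(back, "site_meta"), attr(tab, "site_meta"))
  expect_equal(nrow(attr(back, "block_meta")), 3)
})

test_that("select_blocks keeps the first blocks by block number", {
  four_blocks <- dplyr::bind_rows(lapply(1:4, function(b) {
    dplyr::bind_rows(rec("s1", b, "Control", "a"), rec("s1", b, "NPK", "a"))
  }))
  tab <- cover_table(four_blocks)
  out <- select_blocks(tab, 3)
  expect_setequal(unique(out$block), 1:3)

  three <- cover_table(toy_six_rows())
  expect_equal(as.data.frame(select_blocks(three, 3)),
               as.data.frame(three), ignore_attr = TRUE)
})

test_that("sites with too few blocks are dropped and reported", {
  two_blocks <- dplyr::bind_rows(lapply(1:2, function(b) {
    dplyr::bind_rows(rec("s2", b, "Control", "a"), rec("s2", b, "NPK", "a"))
  }))
  tab <- cover_table(dplyr::bind_rows(toy_six_rows(), two_blocks))
  expect_message(out <- select_blocks(tab, 3), "s2")
  expect_setequal(unique(out$site), "s1")
  expect_equal(attr(out, "dropped_sites"), "s2")
})

test_that("block ordering is numeric when labels are numbers, lexicographic otherwise", {
  num <- dplyr::bind_rows(lapply(c(2, 10, 1, 3), function(b) {
    dplyr::bind_rows(rec("s1", b, "Control", "a"), rec("s1", b, "NPK", "a"))
  }))
  out <- select_blocks(cover_table(num), 3)
  expect_setequal(unique(out$block), c(1, 2, 3))  # not 1, 10, 2

  chr <- dplyr::bind_rows(lapply(c("B", "A", "D", "C"), function(b) {
    dplyr::bind_rows(rec("s1", b, "Control", "a"), rec("s1", b, "NPK", "a"))
  }))
  out2 <- select_blocks(cover_table(chr), 3)
  expect_setequal(unique(out2$block), c("A", "B", "C"))
})

test_that("filter_group('all') keeps everything; specific groups drop non-members", {
  df <- dplyr::bind_rows(
    rec("s1", 1:3, "Control", "forb1", lifeform = "forb"),
    rec("s1", 1:3, "NPK", "forb1", lifeform = "forb"),
    rec("s1", 1:3, "Control", "gram1", lifeform = "graminoid"),
    rec("s1", 1:3, "NPK", "gram1", lifeform = "graminoid"))
  tab <- cover_table(df)
  res <- filter_group(tab, "all")
  expect_equal(nrow(res$table), nrow(tab))
  expect_length(res$excluded_sites, 0)

  forb <- filter_group(tab, "forb")
  expect_setequal(unique(forb$table$taxon), "forb1")
  expect_length(forb$excluded_sites, 0)
})

test_that("a site with any empty group subplot is excluded (log(0) rule)", {
  # legumes present everywhere except the NPK subplot of block 2
  df <- dplyr::bind_rows(
    rec("s1", 1:3, "Control", "leg1", lifeform = "legume"),
    rec("s1", c(1, 3), "NPK", "leg1", lifeform = "legume"),
    rec("s1", 1:3, "NPK", "forb1", lifeform = "forb"),
    rec("s1", 2, "NPK", "forb2", lifeform = "forb"),
    rec("s1", 1:3, "Control", "forb1", lifeform = "forb"),
    # a second, complete site
    rec("s2", 1:3, "Control", "leg2", lifeform = "legume"),
    rec("s2", 1:3, "NPK", "leg2", lifeform = "legume"))
  tab <- cover_table(df)
  expect_message(res <- filter_group(tab, "legume"), "s1")
  expect_equal(res$excluded_sites, "s1")
  expect_setequal(unique(res$table$site), "s2")
})

test_that("filtering an all-native table by 'native' is the identity", {
  tab <- cover_table(toy_six_rows())
  res <- filter_group(tab, "native")
  expect_equal(as.data.frame(res$table), as.data.frame(tab),
               ignore_attr = TRUE)
})

test_that("unknown group names are rejected; unknown labels excluded from groups", {
  expect_error(group_spec("shrubbery"), "unknown group")
  df <- dplyr::bind_rows(
    rec("s1", 1:3, "Control", "x", is_native = "unknown"),
    rec("s1", 1:3, "NPK", "x", is_native = "unknown"),
    rec("s1", 1:3, "Control", "nat"),
    rec("s1", 1:3, "NPK", "nat"))
  tab <- cover_table(df)
  res <- filter_group(tab, "native")
  expect_false("x" %in% res$table$taxon)   # unknown not in 'native'
  expect_true("x" %in% filter_group(tab, "all")$table$taxon)
})

test_that("select_blocks then filter_group('all') is idempotent", {
  tab <- ct_from_sets(list(
    Control = list(`1` = c("a", "b"), `2` = c("b"), `3` = c("c")),
    NPK = list(`1` = c("a"), `2` = c("b", "c"), `3` = c("c"))))
  once <- filter_group(select_blocks(tab, 3), "all")$table
  twice <- filter_group(select_blocks(once, 3), "all")$table
  expect_equal(as.data.frame(twice), as.data.frame(once), ignore_attr = TRUE)
})

test_that("collapse_max_cover keeps the per-species maximum of repeat surveys", {
  df <- dplyr::bind_rows(rec("s1", 1, "Control", "a", 5),
                         rec("s1", 1, "Control", "a", 12),
                         rec("s1", 1, "Control", "b", 3))
  out <- collapse_max_cover(df)
  expect_equal(nrow(out), 2)
  expect_equal(out$cover[out$taxon == "a"], 12)
})
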
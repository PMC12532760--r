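# Change analysis: trends, net change, nine-category classification,
# frequencies, continental summaries and category maps.

rec_row <- function(id, year, metric, value, missing = FALSE, class = 1L,
                    extent = 10) {
  tibble::tibble(landscape_id = id, extent_km = extent, year = year,
                 class = class, metric = metric, value = value,
                 missing = missing)
}

test_that("annual summaries use the sample standard deviation", {
  recs <- dplyr::bind_rows(
    rec_row(1:3, 2000L, "CA", c(2, 2, 2)),
    rec_row(1:3, 2001L, "CA", c(1, 2, 3))
  )
  out <- annual_summary(recs)
  expect_equal(out$mean, c(2, 2))
  expect_equal(out$sd, c(0, 1))

  # a group-year whose only record is a missing LSI is omitted, with warning
  recs2 <- dplyr::bind_rows(recs, rec_row(1L, 2002L, "LSI", NA, missing = TRUE))
  expect_warning(out2 <- annual_summary(recs2), "omitted")
  expect_false(any(out2$metric == "LSI"))
})

test_that("net change subtracts endpoint values and flags presence", {
  recs <- dplyr::bind_rows(
    rec_row(1L, 1992L, "CA", 10), rec_row(1L, 2020L, "CA", 14),
    rec_row(1L, 1992L, "LSI", 1.5), rec_row(1L, 2020L, "LSI", 1.2),
    # class present only in 2020: no LSI delta, presence FALSE
    rec_row(2L, 1992L, "CA", 0), rec_row(2L, 2020L, "CA", 3),
    rec_row(2L, 1992L, "LSI", NA, missing = TRUE),
    rec_row(2L, 2020L, "LSI", 1.1)
  )
  nc <- net_change(recs, 1992L, 2020L)
  expect_equal(nc$delta[nc$landscape_id == 1 & nc$metric == "CA"], 4)
  expect_equal(nc$delta[nc$landscape_id == 1 & nc$metric == "LSI"], -0.3)
  expect_true(all(nc$present_both[nc$landscape_id == 1]))
  expect_false(any(nc$landscape_id == 2 & nc$metric == "LSI"))
  expect_false(any(nc$present_both[nc$landscape_id == 2]))

  # identical years: all deltas zero
  same <- net_change(recs, 1992L, 1992L)
  expect_true(all(same$delta == 0))
  expect_error(net_change(recs, 1992L, 2021L), "present")
})

test_that("the nine CA/LSI categories partition every sign combination", {
  expect_equal(classify_ca_lsi(3, 0.2), "CA+LSI+")
  expect_equal(classify_ca_lsi(0, 0), "CA=LSI=")
  expect_equal(classify_ca_lsi(-1, 0), "CA-LSI=")
  expect_equal(classify_ca_lsi(0, -0.1), "CA=LSI-")
  grid <- expand.grid(dca = c(-1, 0, 1), dlsi = c(-1, 0, 1))
  labs <- classify_ca_lsi(grid$dca, grid$dlsi)
  expect_setequal(labs, landpatterns:::CATEGORY_LEVELS)
  # the LSI tolerance absorbs float-division noise only
  expect_equal(classify_ca_lsi(0, 1e-12), "CA=LSI=")
  expect_equal(classify_ca_lsi(0, 1e-6), "CA=LSI+")
})

test_that("classification excludes landscapes lacking the class in either year", {
  net <- tibble::tibble(
    landscape_id = c(1L, 1L, 2L, 2L, 3L),
    extent_km = 10, class = 1L,
    metric = c("CA", "LSI", "CA", "LSI", "CA"),
    delta = c(3, 0.2, 0, 0, 5),
    present_both = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  out <- classify_changes(net)
  expect_equal(out$category[out$landscape_id == 1], "CA+LSI+")
  expect_equal(out$category[out$landscape_id == 2], "CA=LSI=")
  expect_true(out$excluded[out$landscape_id == 3])
  expect_true(is.na(out$category[out$landscape_id == 3]))
})

test_that("category percentages cover all nine labels and sum to 100", {
  cats <- tibble::tibble(
    landscape_id = 1:4, extent_km = 10, class = 1L,
    delta_ca = 0, delta_lsi = 0,
    category = c("CA=LSI=", "CA=LSI=", "CA+LSI+", "CA-LSI-"),
    excluded = FALSE
  )
  freq <- category_frequencies(cats)
  expect_equal(nrow(freq), 9)
  expect_equal(sum(freq$pct), 100, tolerance = 1e-9)
  expect_equal(freq$pct[freq$category == "CA=LSI="], 50)
  expect_equal(freq$pct[freq$category == "CA+LSI+"], 25)
  expect_equal(freq$pct[freq$category == "CA+LSI-"], 0)

  all_excluded <- cats
  all_excluded$excluded <- TRUE
  expect_error(category_frequencies(all_excluded), "no classified")
})

test_that("swapping years negates deltas and mirrors categories", {
  sc <- lulc_scenario(
    40, 40, years = 1992:1996, seed = 31,
    operators = list(list(kind = "expand", source = 44L, rate = 15L))
  )
  ser <- generate_series(sc)$series
  g <- build_grid(ser, 10)
  recs <- apply_absence_rules(compute_series_metrics(ser, g))
  fwd <- net_change(recs, 1992L, 1996L)
  bwd <- net_change(recs, 1996L, 1992L)
  j <- dplyr::inner_join(fwd, bwd,
                         by = c("landscape_id", "extent_km", "class", "metric"))
  expect_equal(j$delta.x, -j$delta.y)

  flip <- function(x) chartr("+-", "-+", x)
  cf <- classify_changes(fwd)
  cb <- classify_changes(bwd)
  jj <- dplyr::inner_join(cf[!cf$excluded, ], cb,
                          by = c("landscape_id", "extent_km", "class"))
  expect_equal(flip(jj$category.x), jj$category.y)
})

test_that("net CA change sums to zero over all classes when masks are constant", {
  sc <- lulc_scenario(
    40, 40, years = 1992:1995, seed = 32,
    operators = list(list(kind = "contract", source = 44L, target = 55L,
                          rate = 10L))
  )
  ser <- generate_series(sc)$series
  g <- build_grid(ser, 10)
  recs <- apply_absence_rules(compute_series_metrics(ser, g, metrics = "CA"))
  nc <- net_change(recs, 1992L, 1995L)
  per_landscape <- tapply(nc$delta, nc$landscape_id, sum)
  expect_equal(as.numeric(per_landscape), rep(0, length(per_landscape)))
})

test_that("continental summaries aggregate deltas per labelled region", {
  net <- tibble::tibble(
    landscape_id = 1:3, extent_km = 10, class = 1L, metric = "CA",
    delta = c(-2, 0, 2), present_both = TRUE
  )
  grid <- tibble::tibble(landscape_id = 1:3, continent = "Euralia")
  out <- continental_net_change(net, grid)
  expect_equal(out$mean, 0)
  expect_equal(out$sd, 2)
  expect_equal(out$n, 3L)
  # relabelling permutes but does not change the statistics
  grid2 <- tibble::tibble(landscape_id = 1:3, continent = "Borealia")
  out2 <- continental_net_change(net, grid2)
  expect_equal(out2[, c("mean", "sd", "n")], out[, c("mean", "sd", "n")])
})

test_that("category maps place codes at grid positions with 0 for excluded", {
  ser <- matrix_series(matrix(44L, 20, 30))
  g <- build_grid(ser, 10)   # 2 x 3 landscape grid
  cats <- tibble::tibble(
    landscape_id = g$landscape_id[1:3], extent_km = 10, class = 44L,
    delta_ca = c(1, -1, 0), delta_lsi = c(1, -1, 0),
    category = c("CA+LSI+", "CA-LSI-", NA),
    excluded = c(FALSE, FALSE, TRUE)
  )
  cm <- category_map(cats, g)
  expect_equal(dim(cm$map), c(2, 3))
  expect_equal(cm$map[1, 1], match("CA+LSI+", landpatterns:::CATEGORY_LEVELS))
  expect_equal(cm$map[1, 2], match("CA-LSI-", landpatterns:::CATEGORY_LEVELS))
  expect_equal(cm$map[1, 3], 0L)         # excluded
  expect_equal(cm$map[2, ], c(0L, 0L, 0L))  # not classified at all
  expect_equal(nrow(cm$legend), 10)
})
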
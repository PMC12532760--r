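# Neutral-landscape generator: composition, determinism, operators, logs.

test_that("degenerate one-class composition fills every land cell", {
  sc <- lulc_scenario(
    20, 20,
    classes = data.frame(code = 1L, name = "a", proportion = 1),
    ocean_fraction = 0, years = 2000, seed = 3
  )
  g <- generate_initial_map(sc)
  expect_true(all(g == 1L))
})

test_that("scenario validation rejects bad compositions and rates", {
  expect_error(
    lulc_scenario(10, 10, classes = data.frame(code = 1:2, proportion = c(0.6, 0.6))),
    "sum to 1"
  )
  expect_error(lulc_scenario(10, 10, ocean_fraction = 1), "ocean_fraction")
  expect_error(
    lulc_scenario(10, 10, operators = list(list(kind = "explode", source = 1, rate = 1))),
    "operator kind"
  )
  expect_error(
    lulc_scenario(10, 10, operators = list(list(kind = "expand", source = 1, rate = -2))),
    "rate"
  )
  # fewer land cells than classes
  sc <- two_class_scenario(1, 2, ocean = 0.4)
  expect_error(generate_initial_map(sc), "fewer land cells")
})

test_that("realized class frequencies track targets on a 200x200 map", {
  sc <- two_class_scenario(200, 200, density = 0.4, seed = 7, p = c(0.7, 0.3))
  g <- generate_initial_map(sc)
  freq <- c(mean(g == 1L), mean(g == 2L))
  expect_lt(max(abs(freq - c(0.7, 0.3))), 0.05)
})

test_that("identical scenario and seed give bit-identical maps", {
  sc <- lulc_scenario(80, 80, seed = 13, years = 2000)
  expect_identical(generate_initial_map(sc), generate_initial_map(sc))
})

test_that("composition recovery: mean abs deviation < 0.05 over 20 seeds", {
  devs <- vapply(1:20, function(s) {
    sc <- lulc_scenario(200, 200, seed = s, years = 2000)
    g <- generate_initial_map(sc)
    land <- sum(g != sc$ocean_code)
    freq <- vapply(sc$classes$code, function(cc) sum(g == cc), 0) / land
    mean(abs(freq - sc$classes$proportion))
  }, 0)
  expect_lt(mean(devs), 0.05)
})

test_that("ocean mask is contiguous, edge-anchored and near target size", {
  sc <- lulc_scenario(100, 100, ocean_fraction = 0.2, seed = 5, years = 2000)
  g <- generate_initial_map(sc)
  ocean <- g == sc$ocean_code
  expect_equal(sum(ocean), round(0.2 * length(g)), tolerance = 0.02)
  expect_equal(oracle_components(ocean, 4), 1)
  border <- c(ocean[1, ], ocean[100, ], ocean[, 1], ocean[, 100])
  expect_true(any(border))
})

test_that("expand converts exactly `rate` adjacent cells and logs them", {
  g <- matrix(2L, 20, 20)
  g[10, 10] <- 1L
  res <- apply_change_operator(g, list(kind = "expand", source = 1L, rate = 10L),
                               seed = 1)
  expect_equal(sum(res$grid == 1L) - 1, 10)
  expect_equal(nrow(res$log), 10)
  expect_true(all(res$log$to_class == 1L))
  # logged coordinates really are the changed cells
  changed <- which(res$grid != g)
  logged <- (res$log$col - 1L) * 20L + res$log$row
  expect_setequal(logged, changed)
})

test_that("expand never modifies ocean or NoData cells", {
  g <- matrix(0L, 10, 10)       # all ocean...
  g[5:6, 5:6] <- 1L             # ...except a small island
  res <- apply_change_operator(g, list(kind = "expand", source = 1L, rate = 50L),
                               seed = 2)
  expect_identical(res$grid, g)  # nothing available to convert
  expect_equal(nrow(res$log), 0)
})

test_that("zero-rate operators are the identity with an empty log", {
  g <- matrix(2L, 8, 8)
  g[3:5, 3:5] <- 1L
  res <- apply_change_operator(g, list(kind = "contract", source = 1L,
                                       target = 2L, rate = 0L))
  expect_identical(res$grid, g)
  expect_equal(nrow(res$log), 0)
})

test_that("contract removes boundary cells of the source class", {
  g <- matrix(2L, 8, 8)
  g[3:5, 3:5] <- 1L
  res <- apply_change_operator(g, list(kind = "contract", source = 1L,
                                       target = 2L, rate = 4L), seed = 3)
  expect_equal(sum(res$grid == 1L), 5)
  expect_true(all(res$log$operator == "contract"))
  # the interior core cell (4,4) cannot be removed first: it is no boundary
  expect_false(any(res$log$row == 4 & res$log$col == 4))
})

test_that("fragment severs a 1-wide corridor, raising the patch count", {
  w <- dumbbell_window(code = 1L, bg = 2L)
  res <- apply_change_operator(w, list(kind = "fragment", source = 1L,
                                       target = 2L, rate = 1L), seed = 4)
  expect_equal(label_patches(res$grid, 1L)$count, 2)
  expect_equal(nrow(res$log), 1)
})

test_that("convert relabels whole smallest patches within the cell budget", {
  g <- matrix(9L, 10, 10)
  g[1, 1] <- 1L                  # size-1 patch
  g[5:6, 5:6] <- 1L              # size-4 patch
  g[9:10, 1:5] <- 1L             # size-10 patch
  res <- apply_change_operator(g, list(kind = "convert", source = 1L,
                                       target = 2L, rate = 6L), seed = 5)
  # budget 6 covers the size-1 and size-4 patches but not the size-10 one
  expect_equal(sum(res$grid == 2L), 5)
  expect_equal(label_patches(res$grid, 1L)$count, 1)
  expect_error(
    apply_change_operator(g, list(kind = "convert", source = 1L, target = 0L,
                                  rate = 1L)),
    "target"
  )
})

test_that("a no-change scenario yields identical yearly grids", {
  sc <- lulc_scenario(40, 40, years = 1992:1994, seed = 6)
  out <- generate_series(sc)
  expect_identical(out$series$grids[[1]], out$series$grids[[2]])
  expect_identical(out$series$grids[[1]], out$series$grids[[3]])
  expect_equal(nrow(out$log), 0)
})

test_that("yearly expansion grows class area by the rate each year", {
  sc <- lulc_scenario(
    60, 60, ocean_fraction = 0, years = 1992:1996, seed = 8,
    operators = list(list(kind = "expand", source = 44L, rate = 7L))
  )
  out <- generate_series(sc)
  ca <- vapply(out$series$grids, function(g) sum(g == 44L), 0)
  expect_equal(diff(unname(ca)), rep(7, 4))
})

test_that("series generation conserves cells and the ocean mask", {
  sc <- lulc_scenario(
    50, 50, ocean_fraction = 0.15, years = 1992:1997, seed = 9,
    operators = list(
      list(kind = "expand", source = 55L, rate = 12L),
      list(kind = "contract", source = 44L, target = 22L, rate = 6L)
    )
  )
  out <- generate_series(sc)
  ocean0 <- out$series$grids[[1]] == sc$ocean_code
  for (g in out$series$grids) {
    expect_equal(length(g), 2500L)
    expect_identical(g == sc$ocean_code, ocean0)
  }
})

test_that("the truth log replays the series exactly, year by year", {
  sc <- lulc_scenario(
    50, 50, years = 1992:1998, seed = 10,
    operators = list(
      list(kind = "expand", source = 22L, rate = 9L),
      list(kind = "fragment", source = 44L, target = 55L, rate = 1L,
           years = c(1994, 1996))
    )
  )
  out <- generate_series(sc)
  replay <- replay_change_log(out$series$grids[[1]], out$log, sc$years)
  for (i in seq_along(sc$years)) {
    expect_identical(replay[[i]], out$series$grids[[i]])
  }
  # log completeness: per-year changed-cell sets match the grid differences
  for (i in seq_along(sc$years)[-1]) {
    diff_cells <- which(out$series$grids[[i]] != out$series$grids[[i - 1]])
    logged <- out$log[out$log$year == sc$years[i], ]
    expect_setequal((logged$col - 1L) * 50L + logged$row, diff_cells)
  }
})

test_that("generate_series is deterministic in scenario + seed", {
  sc <- lulc_scenario(
    40, 40, years = 1992:1995, seed = 21,
    operators = list(list(kind = "expand", source = 44L, rate = 5L))
  )
  a <- generate_series(sc)
  b <- generate_series(sc)
  expect_identical(a$series$grids, b$series$grids)
  expect_identical(a$log, b$log)
})
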
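#' Tessellate a raster series into square landscapes of one extent
#'
#' Builds a regular grid of square, non-overlapping windows of
#' `extent_km` side length, anchored at the raster's top-left origin.
#' Trailing partial rows/columns are dropped so every landscape is
#' full-sized, and windows that are entirely ocean or NoData in every
#' year are removed (they carry no terrestrial information).
#'
#' @param series An [lulc_series()].
#' @param extent_km Landscape side length in km; must be an integer
#'   multiple of the cell size.
#' @return A tibble of class `landscape_grid` with columns `landscape_id`,
#'   `extent_km`, `cells_per_side`, `grid_row`, `grid_col`, `row0`, `col0`
#'   (1-based top-left cell of the window), `centroid_x`, `centroid_y`
#'   (projected km) and `continent` (NA until [assign_continents()]).
#' @export
build_grid <- function(series, extent_km) {
  cell <- series$cell_size_km
  cps_f <- extent_km / cell
  cps <- as.integer(round(cps_f))
  lp_validate(abs(cps_f - cps) <= 1e-9 && cps >= 1L,
              "extent_km (", extent_km, ") must be an integer multiple of the ",
              "cell size (", cell, " km)")
  g1 <- series$grids[[1]]
  n_wr <- nrow(g1) %/% cps
  n_wc <- ncol(g1) %/% cps
  lp_validate(n_wr >= 1L && n_wc >= 1L,
              "raster smaller than one landscape of extent ", extent_km, " km")

  # a window is removable iff every cell is ocean or NoData in every year
  removable_codes <- c(ocean_codes(series$catalog), series$nodata)
  removable <- Reduce(`&`, lapply(series$grids, function(g) {
    matrix(g %in% removable_codes, nrow(g), ncol(g))
  }))

  rows <- list()
  id <- 0L
  for (wr in seq_len(n_wr)) {
    r0 <- (wr - 1L) * cps + 1L
    for (wc in seq_len(n_wc)) {
      c0 <- (wc - 1L) * cps + 1L
      id <- id + 1L
      if (all(removable[r0:(r0 + cps - 1L), c0:(c0 + cps - 1L)])) next
      rows[[length(rows) + 1L]] <- list(
        landscape_id = id, grid_row = wr, grid_col = wc, row0 = r0, col0 = c0
      )
    }
  }
  if (length(rows) == 0L) {
    lp_stop("no landscape survives the all-ocean removal rule at extent ",
            extent_km, " km")
  }
  out <- dplyr::bind_rows(rows)
  out$extent_km <- extent_km
  out$cells_per_side <- cps
  out$centroid_x <- series$origin[1] + (out$col0 - 1 + cps / 2) * cell
  out$centroid_y <- series$origin[2] - (out$row0 - 1 + cps / 2) * cell
  out$continent <- NA_character_
  out <- out[, c("landscape_id", "extent_km", "cells_per_side", "grid_row",
                 "grid_col", "row0", "col0", "centroid_x", "centroid_y",
                 "continent")]
  attr(out, "n_grid_rows") <- n_wr
  attr(out, "n_grid_cols") <- n_wc
  class(out) <- c("landscape_grid", class(out))
  out
}

#' Extract one landscape window from a raster series
#'
#' @param series An [lulc_series()].
#' @param grid A [build_grid()] tibble.
#' @param landscape_id A landscape id present in `grid`.
#' @param year A year present in the series.
#' @return The square integer sub-matrix for that window (a copy; the
#'   series is never mutated).
#' @export
extract_landscape <- function(series, grid, landscape_id, year) {
  i <- match(landscape_id, grid$landscape_id)
  if (is.na(i)) lp_stop("unknown landscape_id: ", landscape_id)
  yi <- match(as.integer(year), series$years)
  if (is.na(yi)) lp_stop("year ", year, " not in series")
  cps <- grid$cells_per_side[i]
  r0 <- grid$row0[i]
  c0 <- grid$col0[i]
  series$grids[[yi]][r0:(r0 + cps - 1L), c0:(c0 + cps - 1L), drop = FALSE]
}

#' Compute metric records for every landscape and year
#'
#' Runs the metrics engine over all (landscape, year, land class)
#' combinations of one landscape grid and returns long-format records,
#' sorted by landscape, year, class and metric so output is independent
#' of the worker count.
#'
#' @param series An [lulc_series()].
#' @param grid A [build_grid()] tibble.
#' @param config A [metric_config()]; its `cell_size_km` is overridden by
#'   the series' cell size.
#' @param years Years to compute (default all in the series).
#' @param metrics Metric names (default all six).
#' @param classes Land-class codes (default all land classes).
#' @param workers Number of forked workers for the per-landscape loop
#'   (default 1; results are identical for any worker count).
#' @return Tibble with columns `landscape_id`, `extent_km`, `year`,
#'   `class`, `metric`, `value`, `missing`.
#' @export
compute_series_metrics <- function(series, grid, config = metric_config(),
                                   years = NULL, metrics = metric_catalog()$metric,
                                   classes = NULL, workers = 1L) {
  years <- as.integer(years %||% series$years)
  lp_validate(all(years %in% series$years), "requested year not in series")
  classes <- as.integer(classes %||% land_codes(series$catalog))
  classes <- intersect(classes, land_codes(series$catalog))
  config$cell_size_km <- series$cell_size_km
  yi <- match(years, series$years)
  cps <- grid$cells_per_side[1]
  n_cls <- length(classes)
  n_met <- length(metrics)
  block <- n_cls * n_met * length(years)

  one_landscape <- function(i) {
    r0 <- grid$row0[i]
    c0 <- grid$col0[i]
    vals <- numeric(block)
    miss <- logical(block)
    at <- 0L
    for (y in yi) {
      w <- series$grids[[y]][r0:(r0 + cps - 1L), c0:(c0 + cps - 1L), drop = FALSE]
      for (code in classes) {
        mv <- metric_values(w, code, config, metrics)
        vals[at + seq_len(n_met)] <- mv$values
        miss[at + seq_len(n_met)] <- mv$missing
        at <- at + n_met
      }
    }
    list(values = vals, missing = miss)
  }

  idx <- seq_len(nrow(grid))
  res <- if (workers > 1L) {
    parallel::mclapply(idx, one_landscape, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(idx, one_landscape)
  }

  out <- tibble::tibble(
    landscape_id = rep(grid$landscape_id, each = block),
    extent_km = grid$extent_km[1],
    year = rep(rep(years, each = n_cls * n_met), times = nrow(grid)),
    class = rep(rep(classes, each = n_met), times = nrow(grid) * length(years)),
    metric = rep(metrics, times = nrow(grid) * length(years) * n_cls),
    value = unlist(lapply(res, `[[`, "values"), use.names = FALSE),
    missing = unlist(lapply(res, `[[`, "missing"), use.names = FALSE)
  )
  dplyr::arrange(out, .data$landscape_id, .data$year, .data$class, .data$metric)
}
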
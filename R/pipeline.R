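# End-to-end orchestration: simulate/load -> crop -> grids -> metrics ->
# absence rules -> scaling -> change analysis -> CSV outputs + manifest.
# Outputs are sorted before writing so re-running with the same config and
# seed -- at any worker count -- reproduces every CSV byte-for-byte.

#' Build and validate a pipeline run configuration
#'
#' @param scenario An [lulc_scenario()] (synthetic input mode), or `NULL`
#'   when `raster_paths` is given.
#' @param raster_paths Character vector of yearly `.asc` rasters (raster
#'   input mode).
#' @param catalog Class catalog for raster mode.
#' @param region Optional region (see [read_region_geojson()]) to crop to.
#' @param continents Optional labelled region for continental summaries.
#' @param extents_km Landscape side lengths in km.
#' @param metric_cfg A [metric_config()].
#' @param r2_threshold Scaling R-squared threshold (default 0.98).
#' @param change_years `c(year0, year1)` for the net-change stage;
#'   default first and last year.
#' @param out_dir Output directory.
#' @param seed Integer seed for the whole run.
#' @param workers Worker count for the metrics stage.
#' @param write_rasters Also write the (synthetic) series as `.asc` files?
#'   Default `FALSE`.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(scenario = NULL, raster_paths = NULL,
                       catalog = lulc_catalog(), region = NULL,
                       continents = NULL, extents_km = c(10, 20, 40),
                       metric_cfg = metric_config(), r2_threshold = 0.98,
                       change_years = NULL, out_dir = tempfile("lp_run_"),
                       seed = 1L, workers = 1L, write_rasters = FALSE) {
  lp_validate(xor(is.null(scenario), is.null(raster_paths)),
              "give exactly one of scenario or raster_paths")
  cell <- if (!is.null(scenario)) scenario$cell_size_km else
    read_asc_raster(raster_paths[1])$cell_size
  for (e in extents_km) {
    cps <- e / cell
    lp_validate(e > 0 && abs(cps - round(cps)) <= 1e-9,
                "extent ", e, " km is not a positive integer multiple of the ",
                "cell size (", cell, " km)")
  }
  years <- if (!is.null(scenario)) scenario$years else NULL
  if (!is.null(change_years)) {
    lp_validate(length(change_years) == 2L && change_years[1] < change_years[2],
                "change_years must be c(year0, year1) with year0 < year1")
    if (!is.null(years)) {
      lp_validate(all(change_years %in% years),
                  "change_years must lie within the scenario years")
    }
  }
  structure(
    list(
      scenario = scenario, raster_paths = raster_paths, catalog = catalog,
      region = region, continents = continents, extents_km = extents_km,
      metric_cfg = metric_cfg, r2_threshold = r2_threshold,
      change_years = change_years, out_dir = out_dir, seed = as.integer(seed),
      workers = as.integer(workers), write_rasters = isTRUE(write_rasters)
    ),
    class = "run_config"
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    lp_stop("stage '", name, "' failed: ", conditionMessage(e),
            class = "lp_stage_error")
  })
}

write_output <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full landscape-pattern pipeline
#'
#' Executes simulate/load, optional crop, grid construction per extent,
#' metric computation, absence rules, scaling screening (when three or
#' more extents are configured), and change analysis, writing CSV outputs
#' and a JSON run manifest to the configured directory.  Identical config
#' and seed reproduce identical outputs byte-for-byte, independent of the
#' worker count.  Any stage error aborts with the stage name.
#'
#' @param config A [run_config()] (or an [lulc_scenario()], used with
#'   default settings).
#' @return Invisibly, a list with the in-memory stage outputs (`series`,
#'   `truth_log`, `grids`, `records`, `scaling_fits`, `scaling_verdicts`,
#'   `trends`, `net`, `categories`, `frequencies`, `continental`,
#'   `manifest`) and `paths` of the written files.
#' @export
run_pipeline <- function(config) {
  if (inherits(config, "lulc_scenario")) config <- run_config(scenario = config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  paths <- character()

  truth_log <- NULL
  if (!is.null(config$scenario)) {
    sim <- run_stage("simulate", generate_series(config$scenario))
    series <- sim$series
    truth_log <- sim$log
    paths["truth_log"] <- write_output(truth_log, config$out_dir, "truth_log.csv")
    if (config$write_rasters) {
      run_stage("simulate", write_series(series, file.path(config$out_dir, "rasters")))
    }
  } else {
    series <- run_stage("load", load_series(config$raster_paths, config$catalog))
  }

  if (!is.null(config$region)) {
    series <- run_stage("crop", crop_to_polygon(series, config$region))
  }

  grids <- list()
  recs <- list()
  for (e in config$extents_km) {
    g <- run_stage("grid", build_grid(series, e))
    if (!is.null(config$continents)) {
      g <- run_stage("grid", assign_continents(g, config$continents))
    }
    grids[[as.character(e)]] <- g
    paths[paste0("grid_", e)] <- write_output(
      as.data.frame(g), config$out_dir, sprintf("grid_%gkm.csv", e)
    )
    recs[[as.character(e)]] <- run_stage(
      "metrics",
      compute_series_metrics(series, g, config$metric_cfg,
                             workers = config$workers)
    )
  }
  records <- run_stage("metrics", apply_absence_rules(dplyr::bind_rows(recs)))
  paths["metrics"] <- write_output(records, config$out_dir, "metrics.csv")

  scaling_fits <- NULL
  scaling_verdicts <- NULL
  if (length(config$extents_km) >= 3L) {
    scaling_fits <- run_stage("scaling", fit_all_scaling(records))
    scaling_verdicts <- run_stage("scaling", {
      dplyr::bind_rows(lapply(unique(scaling_fits$metric), function(m) {
        v <- classify_scale_invariant(
          scaling_fits[scaling_fits$metric == m, , drop = FALSE],
          config$r2_threshold
        )
        tibble::tibble(metric = m, verdict = v$verdict, reason = v$reason)
      }))
    })
    paths["scaling_fits"] <- write_output(scaling_fits, config$out_dir,
                                          "scaling_fits.csv")
    paths["scaling_verdicts"] <- write_output(scaling_verdicts, config$out_dir,
                                              "scaling_verdicts.csv")
  }

  change_years <- config$change_years %||% range(series$years)
  has_continents <- !is.null(config$continents)
  trends <- run_stage("change", suppressWarnings(
    annual_summary(records, grids[[1]], by_continent = FALSE)
  ))
  paths["trends"] <- write_output(trends, config$out_dir, "trends.csv")
  net <- run_stage("change", net_change(records, change_years[1], change_years[2]))
  paths["net_change"] <- write_output(net, config$out_dir, "net_change.csv")
  categories <- run_stage("change", classify_changes(net))
  paths["categories"] <- write_output(categories, config$out_dir, "categories.csv")
  frequencies <- run_stage("change", category_frequencies(
    categories, by = c("extent_km", "class")
  ))
  paths["category_frequencies"] <- write_output(frequencies, config$out_dir,
                                                "category_frequencies.csv")
  continental <- NULL
  if (has_continents) {
    smallest <- as.character(config$extents_km[1])
    net_small <- net[net$extent_km == config$extents_km[1], , drop = FALSE]
    continental <- run_stage("change",
                             continental_net_change(net_small, grids[[smallest]]))
    paths["continental_net_change"] <- write_output(
      continental, config$out_dir, "continental_net_change.csv"
    )
  }

  manifest <- list(
    config_hash = rlang::hash(list(
      scenario = config$scenario, raster_paths = config$raster_paths,
      extents_km = config$extents_km, metric_cfg = config$metric_cfg,
      r2_threshold = config$r2_threshold, change_years = change_years,
      seed = config$seed
    )),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("landpatterns")),
    years = range(series$years),
    extents_km = config$extents_km,
    rows = lapply(
      list(metrics = records, trends = trends, net_change = net,
           categories = categories, frequencies = frequencies),
      nrow
    )
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  paths["manifest"] <- manifest_path

  invisible(list(
    series = series, truth_log = truth_log, grids = grids, records = records,
    scaling_fits = scaling_fits, scaling_verdicts = scaling_verdicts,
    trends = trends, net = net, categories = categories,
    frequencies = frequencies, continental = continental,
    manifest = manifest, paths = paths
  ))
}

#' Render summary figures from pipeline outputs
#'
#' Reads the stage CSVs from a pipeline output directory and writes PNG
#' figures: mean-vs-extent scaling curves per metric, mean-per-year trend
#' lines per class at the smallest extent, and category-frequency bars.
#' Figure data are deterministic given fixed inputs.
#'
#' @param out_dir A [run_pipeline()] output directory.
#' @param fig_dir Directory for the figures (default `<out_dir>/figures`).
#' @return Invisibly, the written figure paths.
#' @export
report_figures <- function(out_dir, fig_dir = file.path(out_dir, "figures")) {
  need <- function(name, stage) {
    p <- file.path(out_dir, name)
    if (!file.exists(p)) {
      lp_stop("report: missing output '", name, "' from stage '", stage, "'")
    }
    read.csv(p)
  }
  dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()

  metrics <- need("metrics.csv", "metrics")
  if (length(unique(metrics$extent_km)) >= 3L) {
    means <- dplyr::summarise(
      dplyr::group_by(
        metrics[!metrics$missing, , drop = FALSE],
        .data$metric, .data$class, .data$extent_km
      ),
      mean_value = mean(.data$value), .groups = "drop"
    )
    p1 <- ggplot2::ggplot(
      means,
      ggplot2::aes(x = .data$extent_km, y = .data$mean_value,
                   colour = factor(.data$class))
    ) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
      ggplot2::facet_wrap(~metric, scales = "free_y") +
      ggplot2::labs(x = "landscape side length (km)", y = "mean metric value",
                    colour = "class") +
      ggplot2::theme_minimal()
    f <- file.path(fig_dir, "scaling_curves.png")
    ggplot2::ggsave(f, p1, width = 8, height = 5, dpi = 150)
    written["scaling_curves"] <- f
  }

  trends <- need("trends.csv", "change")
  small <- trends[trends$extent_km == min(trends$extent_km), , drop = FALSE]
  p2 <- ggplot2::ggplot(
    small,
    ggplot2::aes(x = .data$year, y = .data$mean, colour = factor(.data$class))
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "year", y = "mean across landscapes", colour = "class") +
    ggplot2::theme_minimal()
  f <- file.path(fig_dir, "trends.png")
  ggplot2::ggsave(f, p2, width = 8, height = 5, dpi = 150)
  written["trends"] <- f

  freqs <- need("category_frequencies.csv", "change")
  p3 <- ggplot2::ggplot(
    freqs,
    ggplot2::aes(x = .data$category, y = .data$pct, fill = .data$category)
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_grid(extent_km ~ class) +
    ggplot2::labs(x = NULL, y = "% of classified landscapes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  f <- file.path(fig_dir, "category_frequencies.png")
  ggplot2::ggsave(f, p3, width = 9, height = 5, dpi = 150)
  written["category_frequencies"] <- f

  invisible(written)
}
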
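#' Define a synthetic land-cover scenario
#'
#' A scenario fully determines a synthetic yearly land-cover series: map
#' dimensions, class composition, spatial aggregation of the initial
#' mosaic, a persistent edge-anchored ocean mask, and a list of yearly
#' change operators.  Together with its seed it fixes the output
#' bit-for-bit.
#'
#' @param grid_rows,grid_cols Cell counts of the map.
#' @param cell_size_km Cell side length in km (default 1, matching 1-km
#'   global LULC products).
#' @param classes Tibble/data.frame with columns `code`, `name`,
#'   `proportion`: target fractions of land cells per class.  Proportions
#'   must be non-negative and sum to 1 (within 1e-9).  Defaults to six
#'   classes with realistic global land shares.
#' @param ocean_fraction Fraction of all cells fixed as a contiguous,
#'   edge-anchored ocean blob; in `[0, 1)`.
#' @param cluster_density Percolation probability in (0, 1) controlling
#'   spatial aggregation of the initial mosaic (higher = larger clusters).
#' @param years Integer vector of consecutive years (inclusive range).
#' @param operators List of change operators; each a list with fields
#'   `kind` (one of `"expand"`, `"contract"`, `"fragment"`, `"convert"`),
#'   `source` (class code), `target` (class code; ignored for expand),
#'   `rate` (non-negative integer cells/year) and optional `years`
#'   (`c(from, to)` of map years the operator produces; default all
#'   transition years).
#' @param seed Integer seed.
#' @return An object of class `lulc_scenario`.
#' @export
lulc_scenario <- function(grid_rows, grid_cols, cell_size_km = 1,
                          classes = NULL, ocean_fraction = 0.1,
                          cluster_density = 0.35, years = 1992:2020,
                          operators = list(), seed = 1L) {
  if (is.null(classes)) {
    cat <- lulc_catalog()
    classes <- tibble::tibble(
      code = land_codes(cat),
      name = cat$name[cat$role == "land"],
      proportion = c(0.02, 0.13, 0.20, 0.30, 0.20, 0.15)
    )
  }
  classes <- tibble::as_tibble(classes)
  lp_validate(all(c("code", "proportion") %in% names(classes)),
              "classes needs columns code and proportion")
  if (!"name" %in% names(classes)) classes$name <- paste0("class_", classes$code)
  lp_validate(all(classes$proportion >= 0), "class proportions must be non-negative")
  lp_validate(abs(sum(classes$proportion) - 1) <= 1e-9,
              "class proportions must sum to 1 (got ", sum(classes$proportion), ")")
  lp_validate(ocean_fraction >= 0 && ocean_fraction < 1,
              "ocean_fraction must be in [0, 1)")
  lp_validate(cluster_density > 0 && cluster_density < 1,
              "cluster_density must be in (0, 1)")
  lp_validate(grid_rows >= 1 && grid_cols >= 1, "grid must be non-empty")
  years <- as.integer(years)
  lp_validate(all(diff(years) == 1L), "years must be a consecutive range")
  for (op in operators) {
    lp_validate(!is.null(op$kind) &&
                  op$kind %in% c("expand", "contract", "fragment", "convert"),
                "unknown operator kind: ", op$kind %||% "<missing>")
    lp_validate(is_count(op$rate), "operator rate must be a non-negative integer")
    lp_validate(!is.null(op$source), "operator needs a source class")
  }
  structure(
    list(
      grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
      cell_size_km = cell_size_km, classes = classes,
      ocean_fraction = ocean_fraction, cluster_density = cluster_density,
      years = years, operators = operators, seed = as.integer(seed),
      ocean_code = 0L, nodata = 255L
    ),
    class = "lulc_scenario"
  )
}

#' @export
print.lulc_scenario <- function(x, ...) {
  cat("<lulc_scenario> ", x$grid_rows, "x", x$grid_cols, " cells, ",
      nrow(x$classes), " classes, ocean ", x$ocean_fraction, ", density ",
      x$cluster_density, ", years ", min(x$years), "-", max(x$years), ", ",
      length(x$operators), " operator(s), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Read a scenario from a YAML file
#'
#' @param path Path to a YAML file whose keys mirror the arguments of
#'   [lulc_scenario()] (`classes` as a list of `{code, name, proportion}`
#'   maps, `years` as `[from, to]`, `operators` as a list of maps).
#' @return An `lulc_scenario`.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  classes <- NULL
  if (!is.null(y$classes)) {
    classes <- dplyr::bind_rows(lapply(y$classes, tibble::as_tibble))
  }
  yrs <- y$years
  if (length(yrs) == 2L) yrs <- yrs[[1]]:yrs[[2]]
  lulc_scenario(
    grid_rows = y$grid_rows, grid_cols = y$grid_cols,
    cell_size_km = y$cell_size_km %||% 1, classes = classes,
    ocean_fraction = y$ocean_fraction %||% 0.1,
    cluster_density = y$cluster_density %||% 0.35,
    years = yrs %||% 1992:2020,
    operators = y$operators %||% list(), seed = y$seed %||% 1L
  )
}

# catalog implied by a scenario: its land classes plus an ocean class
scenario_catalog <- function(scenario) {
  tibble::tibble(
    code = c(as.integer(scenario$classes$code), scenario$ocean_code),
    name = c(scenario$classes$name, "ocean"),
    role = c(rep("land", nrow(scenario$classes)), "ocean")
  )
}
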
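# Landscape-pattern change: annual trends, per-landscape net change
# between two years, the nine-category CA/LSI classification, category
# frequencies and continental summaries.

CATEGORY_LEVELS <- c(
  "CA+LSI+", "CA+LSI-", "CA+LSI=",
  "CA-LSI+", "CA-LSI-", "CA-LSI=",
  "CA=LSI+", "CA=LSI-", "CA=LSI="
)

#' Annual mean and standard deviation of metrics across landscapes
#'
#' Summarises metric records per extent, class, metric and year
#' (optionally per continent), using the sample (n-1) standard deviation.
#' Missing records (undefined LSI) are excluded; groups whose records are
#' all missing in a year are omitted with a warning.
#'
#' @param records Metric records with absence rules applied.
#' @param grid Optional [build_grid()] tibble with continents assigned;
#'   required when `by_continent = TRUE`.
#' @param by_continent Split by continent? Default `FALSE`.
#' @return Tibble with the grouping columns plus `mean`, `sd`, `n`.
#' @export
annual_summary <- function(records, grid = NULL, by_continent = FALSE) {
  if (by_continent) {
    lp_validate(!is.null(grid) && !all(is.na(grid$continent)),
                "by_continent needs a grid with continents assigned")
    records <- dplyr::left_join(
      records, grid[, c("landscape_id", "continent")], by = "landscape_id"
    )
  }
  keys <- c("extent_km", "class", "metric", "year",
            if (by_continent) "continent")
  full <- dplyr::distinct(records[, keys, drop = FALSE])
  kept <- records[!records$missing, , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(kept, dplyr::across(dplyr::all_of(keys))),
    mean = mean(.data$value), sd = sd(.data$value), n = dplyr::n(),
    .groups = "drop"
  )
  dropped <- nrow(full) - nrow(out)
  if (dropped > 0) {
    warning(dropped, " group-year(s) had only missing values and were omitted")
  }
  dplyr::arrange(out, dplyr::across(dplyr::all_of(keys)))
}

#' Per-landscape net change between two years
#'
#' Computes `value(year1) - value(year0)` per landscape, class and
#' metric.  A delta is emitted only when both endpoints are defined (for
#' LSI this requires the class to be present in both years).  The
#' `present_both` flag records whether the class had CA > 0 in both years
#' -- the selection rule for the CA/LSI change classification.
#'
#' @param records Metric records (absence rules applied) containing both
#'   years and the CA metric.
#' @param year0,year1 The two years to compare.
#' @param min_presence_cells Minimum cell count for "contains the class";
#'   default 1 (any cell).
#' @return Tibble with `landscape_id`, `extent_km`, `class`, `metric`,
#'   `delta`, `present_both`.
#' @export
net_change <- function(records, year0, year1, min_presence_cells = 1L) {
  lp_validate(all(c(year0, year1) %in% records$year),
              "both years must be present in the records")
  keys <- c("landscape_id", "extent_km", "class", "metric")
  r0 <- records[records$year == year0, , drop = FALSE]
  r1 <- records[records$year == year1, , drop = FALSE]
  j <- dplyr::inner_join(r0, r1, by = keys, suffix = c("0", "1"))
  j <- j[!j$missing0 & !j$missing1, , drop = FALSE]
  j$delta <- j$value1 - j$value0

  # presence flag from the CA rows; cell counts recovered from areas only
  # up to the unknown cell size, so compare areas against a zero threshold
  # scaled by min_presence_cells' share of the smallest observed positive CA
  ca <- j[j$metric == "CA", c(keys[1:3], "value0", "value1"), drop = FALSE]
  pos_ca <- c(ca$value0, ca$value1)
  cell_area <- if (any(pos_ca > 0)) min(pos_ca[pos_ca > 0]) else 1
  thr <- (min_presence_cells - 0.5) * cell_area
  ca$present_both <- ca$value0 > thr & ca$value1 > thr
  j <- dplyr::left_join(j, ca[, c(keys[1:3], "present_both")], by = keys[1:3])
  j$present_both[is.na(j$present_both)] <- FALSE
  out <- j[, c(keys, "delta", "present_both")]
  dplyr::arrange(out, .data$landscape_id, .data$class, .data$metric)
}

sign_symbol <- function(delta, tol) {
  ifelse(delta > tol, "+", ifelse(delta < -tol, "-", "="))
}

#' Classify a (dCA, dLSI) pair into one of nine directional categories
#'
#' The sign of the net change in class area and in the Landscape Shape
#' Index is mapped to `+`, `-` or `=`, giving the nine exhaustive labels
#' `CA+LSI+` ... `CA=LSI=`.  "No change" means `|delta| <= tolerance`:
#' exact zero for CA (cell counts are integers) and a small tolerance for
#' LSI guarding only against float division noise, since both LSI terms
#' are integers.
#'
#' @param delta_ca,delta_lsi Net changes (vectorised).
#' @param tol_ca Tolerance for "no change" in CA (default 0, exact).
#' @param tol_lsi Tolerance for "no change" in LSI (default 1e-9; LSI is
#'   of order 1, so this is effectively a relative tolerance).
#' @return Character vector of category labels.
#' @export
classify_ca_lsi <- function(delta_ca, delta_lsi, tol_ca = 0, tol_lsi = 1e-9) {
  paste0("CA", sign_symbol(delta_ca, tol_ca),
         "LSI", sign_symbol(delta_lsi, tol_lsi))
}

#' Nine-category CA/LSI change classification per landscape
#'
#' Applies [classify_ca_lsi()] to the net-change records of one or more
#' classes.  Only landscapes containing the class in both years
#' (`present_both`) are classified; the others are flagged `excluded`
#' with an `NA` category (they appear grey in the category maps).
#'
#' @param net Output of [net_change()] containing CA and LSI deltas.
#' @inheritParams classify_ca_lsi
#' @return Tibble with `landscape_id`, `extent_km`, `class`, `delta_ca`,
#'   `delta_lsi`, `category`, `excluded`.
#' @export
classify_changes <- function(net, tol_ca = 0, tol_lsi = 1e-9) {
  wide <- tidyr::pivot_wider(
    net[net$metric %in% c("CA", "LSI"), , drop = FALSE],
    names_from = "metric", values_from = "delta"
  )
  if (!"LSI" %in% names(wide)) wide$LSI <- NA_real_
  lp_validate("CA" %in% names(wide), "net-change records must include CA")
  out <- tibble::tibble(
    landscape_id = wide$landscape_id,
    extent_km = wide$extent_km,
    class = wide$class,
    delta_ca = wide$CA,
    delta_lsi = wide$LSI,
    excluded = !wide$present_both | is.na(wide$LSI)
  )
  out$category <- ifelse(
    out$excluded, NA_character_,
    classify_ca_lsi(out$delta_ca, out$delta_lsi, tol_ca, tol_lsi)
  )
  dplyr::arrange(out, .data$landscape_id, .data$class)
}

#' Percentage of landscapes in each of the nine change categories
#'
#' Percentages are taken over classified (non-excluded) landscapes and
#' always cover all nine labels, summing to 100 per group.
#'
#' @param categories Output of [classify_changes()], possibly joined with
#'   a `continent` column.
#' @param by Character vector of grouping columns (e.g. `"class"`,
#'   `c("class", "continent")`, `c("class", "extent_km")`); default
#'   `"class"`.
#' @return Tibble with the grouping columns plus `category`, `n`, `pct`.
#' @export
category_frequencies <- function(categories, by = "class") {
  cls <- categories[!categories$excluded, , drop = FALSE]
  lp_validate(nrow(cls) > 0, "no classified landscapes in scope")
  cls$category <- factor(cls$category, levels = CATEGORY_LEVELS)
  out <- dplyr::count(
    dplyr::group_by(cls, dplyr::across(dplyr::all_of(by))),
    .data$category, .drop = FALSE, name = "n"
  )
  out <- dplyr::mutate(out, pct = 100 * .data$n / sum(.data$n))
  out <- dplyr::ungroup(out)
  out$category <- as.character(out$category)
  out
}

#' Average net change per continent
#'
#' Mean and sample standard deviation of the per-landscape deltas over
#' each continent's landscapes, per class and metric.  Landscapes outside
#' every continent polygon are reported under `"unassigned"`.
#'
#' @param net Output of [net_change()].
#' @param grid A [build_grid()] tibble with continents assigned.
#' @return Tibble with `continent`, `class`, `metric`, `mean`, `sd`, `n`.
#' @export
continental_net_change <- function(net, grid) {
  lp_validate(!all(is.na(grid$continent)),
              "grid has no continents assigned; run assign_continents() first")
  j <- dplyr::left_join(net, grid[, c("landscape_id", "continent")],
                        by = "landscape_id")
  out <- dplyr::summarise(
    dplyr::group_by(j, .data$continent, .data$class, .data$metric),
    mean = mean(.data$delta), sd = sd(.data$delta), n = dplyr::n(),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$continent, .data$class, .data$metric)
}

#' Rasterise the change categories of one class onto the landscape grid
#'
#' Produces an integer matrix at landscape resolution: codes 1..9 for the
#' nine categories (in the order of the legend) and 0 for landscapes that
#' were excluded (class absent in one or both years) or removed from the
#' grid.
#'
#' @param categories Output of [classify_changes()] for a single class.
#' @param grid The [build_grid()] tibble the categories were computed on.
#' @return List with `map` (integer matrix `n_grid_rows` x `n_grid_cols`)
#'   and `legend` (tibble `code`, `category`).
#' @export
category_map <- function(categories, grid) {
  lp_validate(length(unique(categories$class)) <= 1L,
              "category_map expects categories of a single class")
  n_wr <- attr(grid, "n_grid_rows") %||% max(grid$grid_row)
  n_wc <- attr(grid, "n_grid_cols") %||% max(grid$grid_col)
  map <- matrix(0L, n_wr, n_wc)
  j <- dplyr::inner_join(
    categories, grid[, c("landscape_id", "grid_row", "grid_col")],
    by = "landscape_id"
  )
  code <- match(j$category, CATEGORY_LEVELS)
  code[is.na(code)] <- 0L
  map[(j$grid_col - 1L) * n_wr + j$grid_row] <- code
  list(
    map = map,
    legend = tibble::tibble(
      code = 0:9,
      category = c("absent/excluded", CATEGORY_LEVELS)
    )
  )
}
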
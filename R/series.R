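#' Default land-cover class catalog
#'
#' A class catalog modelled on global LULC products that carry six land
#' classes plus ocean and inland water: integer cell codes, human-readable
#' names and a role flag.  The `role` column distinguishes `"land"` classes
#' (for which metrics are computed), `"water"` (inland water; dropped at the
#' record level) and `"ocean"` (drives all-ocean landscape removal).
#'
#' @return A tibble with columns `code`, `name`, `role`.
#' @export
lulc_catalog <- function() {
  tibble::tibble(
    code = c(11L, 22L, 33L, 44L, 55L, 66L, 77L, 0L),
    name = c(
      "urban", "cropland", "pasture_rangeland", "forest",
      "grass_shrubland", "sparse_vegetation", "water", "ocean"
    ),
    role = c(rep("land", 6L), "water", "ocean")
  )
}

land_codes <- function(catalog) catalog$code[catalog$role == "land"]
ocean_codes <- function(catalog) catalog$code[catalog$role == "ocean"]
water_codes <- function(catalog) catalog$code[catalog$role %in% c("ocean", "water")]

#' Construct a yearly categorical raster series
#'
#' Container for co-registered single-band categorical grids, one per year.
#' Grids are integer matrices with row 1 at the top (north).  All years must
#' share dimensions; the projection is assumed equal-area so that cell
#' counts translate directly into areas.
#'
#' @param grids List of integer matrices, one per year, identical dimensions.
#' @param years Integer vector of years, same length as `grids`.
#' @param cell_size_km Cell side length in kilometres.
#' @param catalog Class catalog tibble (see [lulc_catalog()]).
#' @param nodata Integer NoData code (default 255).
#' @param origin Numeric `c(x, y)` of the raster's top-left corner in
#'   projected km; defaults to `c(0, nrow * cell_size_km)`.
#' @param crs Free-text tag for the (equal-area) projection.
#' @return An object of class `lulc_series`.
#' @export
lulc_series <- function(grids, years, cell_size_km = 1, catalog = lulc_catalog(),
                        nodata = 255L, origin = NULL, crs = "synthetic-equal-area") {
  lp_validate(length(grids) >= 1L, "a series needs at least one year")
  lp_validate(length(grids) == length(years), "grids and years differ in length")
  lp_validate(cell_size_km > 0, "cell_size_km must be positive")
  dims <- vapply(grids, dim, integer(2))
  for (i in seq_along(grids)) {
    if (!all(dims[, i] == dims[, 1])) {
      lp_stop("grid geometry mismatch for year ", years[i],
              " (", dims[1, i], "x", dims[2, i], " vs ",
              dims[1, 1], "x", dims[2, 1], ")", class = "lp_load_error")
    }
  }
  known <- c(catalog$code, as.integer(nodata))
  seen <- sort(unique(unlist(lapply(grids, function(g) unique(as.vector(g))))))
  unknown <- setdiff(seen, known)
  if (length(unknown) > 0) {
    lp_stop("codes not in catalog: ", paste(unknown, collapse = ", "),
            class = "lp_load_error")
  }
  ord <- order(years)
  grids <- lapply(grids[ord], function(g) {
    storage.mode(g) <- "integer"
    g
  })
  years <- as.integer(years[ord])
  names(grids) <- years
  origin <- origin %||% c(0, nrow(grids[[1]]) * cell_size_km)
  structure(
    list(
      grids = grids, years = years, cell_size_km = cell_size_km,
      catalog = catalog, nodata = as.integer(nodata),
      origin = origin, crs = crs
    ),
    class = "lulc_series"
  )
}

#' @export
print.lulc_series <- function(x, ...) {
  g <- x$grids[[1]]
  cat(
    "<lulc_series> ", length(x$years), " years (", min(x$years), "-",
    max(x$years), "), ", nrow(g), "x", ncol(g), " cells @ ",
    x$cell_size_km, " km, ", sum(x$catalog$role == "land"),
    " land classes, crs: ", x$crs, "\n", sep = ""
  )
  invisible(x)
}

#' Write / read a single-band integer raster as ESRI ASCII grid
#'
#' The ASCII grid (`.asc`) format stores a six-line header (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed
#' by cell values row by row from the top.  It is the package's on-disk
#' raster format: plain text, readable by standard GIS tooling.
#'
#' @param mat Integer matrix (row 1 = top).
#' @param path Output file path.
#' @param cell_size Cell side length in map units (km here).
#' @param nodata NoData code.
#' @param xll,yll Coordinates of the lower-left corner.
#' @return `write_asc_raster()` returns `path` invisibly;
#'   `read_asc_raster()` returns a list with `mat`, `cell_size`, `nodata`,
#'   `xll`, `yll`.
#' @export
write_asc_raster <- function(mat, path, cell_size = 1, nodata = 255L,
                             xll = 0, yll = 0) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(mat)),
    paste("nrows", nrow(mat)),
    paste("xllcorner", format(xll, scientific = FALSE)),
    paste("yllcorner", format(yll, scientific = FALSE)),
    paste("cellsize", format(cell_size, scientific = FALSE)),
    paste("NODATA_value", nodata)
  ), con)
  utils::write.table(mat, con, sep = " ", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_asc_raster
#' @export
read_asc_raster <- function(path) {
  header <- readLines(path, n = 6L)
  kv <- strsplit(trimws(header), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  lp_validate(
    all(c("ncols", "nrows", "cellsize") %in% keys),
    "not an ASCII grid header: ", path
  )
  body <- scan(path, what = integer(), skip = 6L, quiet = TRUE)
  nr <- as.integer(vals[["nrows"]])
  nc <- as.integer(vals[["ncols"]])
  lp_validate(length(body) == nr * nc, "cell count mismatch in ", path)
  list(
    mat = matrix(body, nrow = nr, ncol = nc, byrow = TRUE),
    cell_size = vals[["cellsize"]],
    nodata = as.integer(vals["nodata_value"] %||% 255L),
    xll = unname(vals["xllcorner"] %||% 0),
    yll = unname(vals["yllcorner"] %||% 0)
  )
}

#' Load a yearly raster series from ASCII grid files
#'
#' Reads one `.asc` file per year, validates that all years share geometry
#' and that every cell code is known to the catalog, and returns a series
#' sorted by ascending year.
#'
#' @param paths Character vector of file paths.  Years are taken from
#'   `years` if given, otherwise parsed as the first 4-digit run in each
#'   file name.
#' @param catalog Class catalog tibble.
#' @param years Optional integer years, parallel to `paths`.
#' @param cell_size_km Override for the cell size; by default the header's
#'   `cellsize` is used.
#' @param crs Projection tag (must describe an equal-area projection).
#' @return An [lulc_series()] object.
#' @export
load_series <- function(paths, catalog = lulc_catalog(), years = NULL,
                        cell_size_km = NULL, crs = "unspecified-equal-area") {
  lp_validate(length(paths) >= 1L, "need at least one raster path")
  if (is.null(years)) {
    m <- regmatches(basename(paths), regexpr("[0-9]{4}", basename(paths)))
    lp_validate(length(m) == length(paths),
                "cannot parse a 4-digit year from every file name; pass `years`")
    years <- as.integer(m)
  }
  rasters <- lapply(paths, read_asc_raster)
  base <- rasters[[1]]
  for (i in seq_along(rasters)) {
    r <- rasters[[i]]
    if (!identical(dim(r$mat), dim(base$mat)) ||
        abs(r$cell_size - base$cell_size) > 1e-9 ||
        r$nodata != base$nodata) {
      lp_stop("raster geometry mismatch for year ", years[i], " (", paths[i], ")",
              class = "lp_load_error")
    }
  }
  cell <- cell_size_km %||% base$cell_size
  origin <- c(base$xll, base$yll + nrow(base$mat) * cell)
  lulc_series(
    grids = lapply(rasters, `[[`, "mat"), years = years,
    cell_size_km = cell, catalog = catalog, nodata = base$nodata,
    origin = origin, crs = crs
  )
}

#' Write a raster series to a directory of ASCII grids
#'
#' One file `lulc_<year>.asc` per year.
#'
#' @param series An [lulc_series()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yll <- series$origin[2] - nrow(series$grids[[1]]) * series$cell_size_km
  paths <- vapply(seq_along(series$years), function(i) {
    p <- file.path(dir, sprintf("lulc_%d.asc", series$years[i]))
    write_asc_raster(series$grids[[i]], p, cell_size = series$cell_size_km,
                     nodata = series$nodata, xll = series$origin[1], yll = yll)
    p
  }, character(1))
  invisible(paths)
}
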
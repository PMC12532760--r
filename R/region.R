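# Polygon regions: GeoJSON input, even-odd point-in-polygon containment.
# Regions are lists of features, each `list(name, rings)` where rings are
# two-column (x, y) matrices in the raster's projected coordinates; holes
# are additional rings (even-odd rule).

#' Read labelled polygons from a GeoJSON file
#'
#' Supports FeatureCollections of Polygon and MultiPolygon geometries in
#' the raster's projected coordinate system.  Feature names are taken from
#' the `name` (or `continent`) property.
#'
#' @param path Path to a GeoJSON file.
#' @return A region: list of `list(name, rings)` features.
#' @export
read_region_geojson <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(j$type, "FeatureCollection")) j$features else list(j)
  out <- lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    geom <- f$geometry %||% f
    nm <- f$properties$name %||% f$properties$continent %||% paste0("region_", i)
    ring_mat <- function(ring) {
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    }
    rings <- switch(
      geom$type,
      Polygon = lapply(geom$coordinates, ring_mat),
      MultiPolygon = unlist(lapply(geom$coordinates,
                                   function(poly) lapply(poly, ring_mat)),
                            recursive = FALSE),
      lp_stop("unsupported geometry type: ", geom$type)
    )
    list(name = nm, rings = rings)
  })
  out
}

# convenience: a rectangle region from bounds
region_rectangle <- function(xmin, xmax, ymin, ymax, name = "region") {
  list(list(
    name = name,
    rings = list(cbind(c(xmin, xmax, xmax, xmin, xmin),
                       c(ymin, ymin, ymax, ymax, ymin)))
  ))
}

# even-odd containment of points in one feature; boundary points count as
# inside (documented tie-break: first feature in input order wins)
points_in_feature <- function(x, y, feature) {
  hits <- integer(length(x))
  for (ring in feature$rings) {
    inside <- pracma::inpolygon(x, y, ring[, 1], ring[, 2], boundary = TRUE)
    hits <- hits + as.integer(inside)
  }
  hits %% 2L == 1L
}

# cell-centre coordinates of an nr x nc raster with given top-left origin
cell_centers <- function(nr, nc, cell, origin) {
  cols <- rep(seq_len(nc), each = nr)
  rows <- rep(seq_len(nr), times = nc)
  list(
    x = origin[1] + (cols - 0.5) * cell,
    y = origin[2] - (rows - 0.5) * cell
  )
}

#' Crop a raster series to a polygon region
#'
#' Cells whose centres fall outside the region become NoData; the grid is
#' clipped to the bounding row/column window of the retained cells.  The
#' same crop is applied to every year, so the operation is idempotent.
#'
#' @param series An [lulc_series()].
#' @param region A region (from [read_region_geojson()]) or a single
#'   two-column ring matrix.
#' @return The cropped [lulc_series()].
#' @export
crop_to_polygon <- function(series, region) {
  if (is.matrix(region)) region <- list(list(name = "region", rings = list(region)))
  g1 <- series$grids[[1]]
  nr <- nrow(g1)
  nc <- ncol(g1)
  ctr <- cell_centers(nr, nc, series$cell_size_km, series$origin)
  inside <- rep(FALSE, nr * nc)
  for (f in region) {
    inside <- inside | points_in_feature(ctr$x, ctr$y, f)
  }
  if (!any(inside)) lp_stop("region does not intersect the raster")
  inside <- matrix(inside, nr, nc)
  keep_r <- range(which(rowSums(inside) > 0))
  keep_c <- range(which(colSums(inside) > 0))
  rs <- keep_r[1]:keep_r[2]
  cs <- keep_c[1]:keep_c[2]
  sub_inside <- inside[rs, cs, drop = FALSE]
  grids <- lapply(series$grids, function(g) {
    w <- g[rs, cs, drop = FALSE]
    w[!sub_inside] <- series$nodata
    w
  })
  origin <- c(
    series$origin[1] + (keep_c[1] - 1L) * series$cell_size_km,
    series$origin[2] - (keep_r[1] - 1L) * series$cell_size_km
  )
  lulc_series(
    grids = grids, years = series$years, cell_size_km = series$cell_size_km,
    catalog = series$catalog, nodata = series$nodata, origin = origin,
    crs = series$crs
  )
}

#' Assign landscapes to continents by centroid containment
#'
#' Each landscape is labelled by the first polygon feature (in input
#' order) containing its centroid; centroids in no polygon are labelled
#' `"unassigned"`.  The first-feature rule makes shared-boundary ties
#' deterministic.
#'
#' @param grid A [build_grid()] tibble.
#' @param continents A region whose features carry continent names.
#' @return The grid with its `continent` column filled.
#' @export
assign_continents <- function(grid, continents) {
  label <- rep("unassigned", nrow(grid))
  unset <- rep(TRUE, nrow(grid))
  for (f in continents) {
    if (!any(unset)) break
    hit <- points_in_feature(grid$centroid_x[unset], grid$centroid_y[unset], f)
    label[which(unset)[hit]] <- f$name
    unset[which(unset)[hit]] <- FALSE
  }
  grid$continent <- label
  grid
}
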
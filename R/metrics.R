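# Class-level landscape metrics on a square categorical window.
#
# Conventions (all exposed through metric_config):
#   * patch connectivity defaults to 8 (queen), core neighbourhood to 4
#     (rook) with one-cell edge depth;
#   * total edge (TE) excludes the window's outer boundary by default;
#   * the LSI edge term always includes the boundary, so a window entirely
#     covered by one class has LSI = 1;
#   * window border cells are never core (a missing neighbour counts as
#     different), and water/NoData cells count as "different" neighbours.
# Edge lengths are exact integer face counts before scaling by the cell
# size, so TE and the LSI numerator carry no accumulation error.

# connected components of a logical mask; labels matrix + count.
# Uses igraph over an adjacency edge list built from mask shifts.
mask_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  ids <- which(mask)
  n <- length(ids)
  labels <- matrix(0L, nr, nc)
  if (n == 0L) return(list(labels = labels, count = 0L))
  pos <- integer(nr * nc)
  pos[ids] <- seq_len(n)

  pair_idx <- function(a_keep_r, a_keep_c, offset) {
    both <- mask[a_keep_r, a_keep_c, drop = FALSE] &
      mask[a_keep_r + offset[1], a_keep_c + offset[2], drop = FALSE]
    w <- which(both)
    if (length(w) == 0L) return(NULL)
    sub_nr <- length(a_keep_r)
    r <- a_keep_r[idx_row(w, sub_nr)]
    c <- a_keep_c[idx_col(w, sub_nr)]
    i1 <- (c - 1L) * nr + r
    i2 <- (c + offset[2] - 1L) * nr + r + offset[1]
    cbind(pos[i1], pos[i2])
  }

  edges <- list()
  if (nr > 1L) edges$v <- pair_idx(seq_len(nr - 1L), seq_len(nc), c(1L, 0L))
  if (nc > 1L) edges$h <- pair_idx(seq_len(nr), seq_len(nc - 1L), c(0L, 1L))
  if (connectivity == 8L && nr > 1L && nc > 1L) {
    edges$dr <- pair_idx(seq_len(nr - 1L), seq_len(nc - 1L), c(1L, 1L))
    edges$dl <- pair_idx(seq_len(nr - 1L), 1L + seq_len(nc - 1L), c(1L, -1L))
  }
  em <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(em) && nrow(em) > 0L) {
    g <- igraph::add_edges(g, as.vector(t(em)))
  }
  comp <- igraph::components(g)
  labels[ids] <- comp$membership
  list(labels = labels, count = as.integer(comp$no))
}

#' Label the patches of one class in a landscape window
#'
#' A patch is a maximal connected set of same-class cells under the chosen
#' connectivity (4 = rook, 8 = queen).
#'
#' @param window Integer class-code matrix.
#' @param class_code Class to label.
#' @param connectivity 4 or 8 (default 8).
#' @return List with `labels` (integer matrix; 0 for other classes) and
#'   `count` (number of patches; 0 when the class is absent).
#' @export
label_patches <- function(window, class_code, connectivity = 8L) {
  lp_validate(connectivity %in% c(4L, 8L), "connectivity must be 4 or 8")
  mask_components(window == class_code, connectivity = connectivity)
}

#' Class area (CA)
#'
#' Total area of one class in the window: cell count times cell area.
#'
#' @param window Integer class-code matrix.
#' @param class_code Class code.
#' @param cell_size Cell side length in km.
#' @return Area in km^2 (0 when the class is absent).
#' @export
class_area <- function(window, class_code, cell_size = 1) {
  sum(window == class_code) * cell_size^2
}

# internal + (optionally) boundary contrast faces, as an exact integer
edge_faces <- function(window, class_code, count_boundary = FALSE) {
  cls <- window == class_code
  nr <- nrow(cls)
  nc <- ncol(cls)
  faces <- 0L
  if (nr > 1L) {
    faces <- faces + sum(cls[-nr, , drop = FALSE] != cls[-1L, , drop = FALSE])
  }
  if (nc > 1L) {
    faces <- faces + sum(cls[, -nc, drop = FALSE] != cls[, -1L, drop = FALSE])
  }
  if (count_boundary) {
    faces <- faces + sum(cls[1L, ]) + sum(cls[nr, ]) + sum(cls[, 1L]) + sum(cls[, nc])
  }
  as.integer(faces)
}

#' Total edge length (TE)
#'
#' Sum of cell faces separating the class from any different cover
#' (other classes, water, NoData), times the cell size.  Faces on the
#' window's outer boundary are included only when `count_boundary = TRUE`.
#'
#' @inheritParams class_area
#' @param count_boundary Include window-boundary faces? Default `FALSE`.
#' @return Edge length in km.
#' @export
total_edge <- function(window, class_code, cell_size = 1, count_boundary = FALSE) {
  edge_faces(window, class_code, count_boundary) * cell_size
}

#' Minimum possible edge of an n-cell class, in faces
#'
#' The perimeter of the most compact (square-like) polyomino of `n` cells:
#' with `m = floor(sqrt(n))`, the minimum is `4m` when `n = m^2`, `4m + 2`
#' when `n <= m(m + 1)`, and `4m + 4` otherwise.  This is the denominator
#' of the Landscape Shape Index.
#'
#' @param n Non-negative integer cell count(s); vectorised.
#' @return Integer face count(s); 0 for `n = 0`.
#' @export
min_edge_faces <- function(n) {
  lp_validate(all(n >= 0), "n must be non-negative")
  n <- as.numeric(n)
  m <- floor(sqrt(n) + 1e-9)
  out <- ifelse(
    n == 0, 0,
    ifelse(m^2 == n, 4 * m, ifelse(n <= m * (m + 1), 4 * m + 2, 4 * m + 4))
  )
  as.integer(out)
}

#' Landscape Shape Index (LSI)
#'
#' Ratio of the class's total edge length (window boundary included) to
#' the hypothetical minimum edge length of the same number of cells if
#' maximally aggregated.  1 means maximal compactness; larger values mean
#' more complex or disaggregated shapes.  Both numerator and denominator
#' are exact integer face counts, so the ratio is >= 1 whenever defined.
#'
#' @inheritParams class_area
#' @return Dimensionless ratio, or `NA_real_` when the class is absent.
#' @export
lsi <- function(window, class_code) {
  n <- sum(window == class_code)
  if (n == 0L) return(NA_real_)
  edge_faces(window, class_code, count_boundary = TRUE) / min_edge_faces(n)
}

#' Core-area mask of one class
#'
#' A class cell is core iff every neighbour in the chosen neighbourhood
#' exists within the window and carries the same class; missing neighbours
#' at the window border disqualify, so border cells are never core (edge
#' depth is fixed at one cell).
#'
#' @inheritParams class_area
#' @param core_neighborhood 4 or 8 (default 4).
#' @return Logical matrix.
#' @export
core_mask <- function(window, class_code, core_neighborhood = 4L) {
  lp_validate(core_neighborhood %in% c(4L, 8L), "core_neighborhood must be 4 or 8")
  cls <- window == class_code
  shifts <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  if (core_neighborhood == 8L) {
    shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
  }
  core <- cls
  for (s in shifts) core <- core & shift_mask(cls, s[1], s[2])
  core
}

#' Total core area (TCA)
#'
#' Area of the class's core cells (see [core_mask()]).
#'
#' @inheritParams core_mask
#' @param cell_size Cell side length in km.
#' @return Area in km^2.
#' @export
total_core_area <- function(window, class_code, cell_size = 1,
                            core_neighborhood = 4L) {
  sum(core_mask(window, class_code, core_neighborhood)) * cell_size^2
}

#' Number of disjunct core areas (NDCA)
#'
#' Connected-component count of the core mask under the patch
#' connectivity: the number of "patches within patches".
#'
#' @inheritParams core_mask
#' @param connectivity Patch connectivity for the core components (default 8).
#' @return Non-negative integer count.
#' @export
ndca <- function(window, class_code, connectivity = 8L, core_neighborhood = 4L) {
  mask_components(core_mask(window, class_code, core_neighborhood),
                  connectivity = connectivity)$count
}

#' Metric catalog: names, units and absence semantics
#'
#' When a class is absent from a landscape, CA, NP, TE, TCA and NDCA are
#' genuinely zero, whereas LSI is undefined and stays missing.
#'
#' @return Tibble with columns `metric`, `units`, `absent_semantics`.
#' @export
metric_catalog <- function() {
  tibble::tibble(
    metric = c("CA", "NP", "TE", "TCA", "NDCA", "LSI"),
    units = c("km2", "count", "km", "km2", "count", "dimensionless"),
    absent_semantics = c(rep("zero", 5L), "missing")
  )
}

#' Metric computation conventions
#'
#' Bundles the connectivity and boundary conventions so every landscape is
#' measured identically.
#'
#' @param connectivity Patch connectivity for NP and NDCA (default 8).
#' @param core_neighborhood Neighbourhood for core cells (default 4).
#' @param count_boundary Include window-boundary faces in TE? Default
#'   `FALSE` (the LSI edge term always includes them).
#' @param cell_size_km Cell side length in km.
#' @return A list of class `metric_config`.
#' @export
metric_config <- function(connectivity = 8L, core_neighborhood = 4L,
                          count_boundary = FALSE, cell_size_km = 1) {
  lp_validate(connectivity %in% c(4L, 8L), "connectivity must be 4 or 8")
  lp_validate(core_neighborhood %in% c(4L, 8L), "core_neighborhood must be 4 or 8")
  lp_validate(cell_size_km > 0, "cell_size_km must be positive")
  structure(
    list(
      connectivity = as.integer(connectivity),
      core_neighborhood = as.integer(core_neighborhood),
      count_boundary = isTRUE(count_boundary),
      cell_size_km = cell_size_km
    ),
    class = "metric_config"
  )
}

# fast path: values of the requested metrics for one class, no tibbles
metric_values <- function(window, code, config,
                          metrics = metric_catalog()$metric) {
  n <- sum(window == code)
  cs <- config$cell_size_km
  vals <- setNames(rep(NA_real_, length(metrics)), metrics)
  miss <- setNames(rep(FALSE, length(metrics)), metrics)
  if (n == 0L) {
    vals[metrics != "LSI"] <- 0
    if ("LSI" %in% metrics) miss["LSI"] <- TRUE
    return(list(values = vals, missing = miss))
  }
  if ("CA" %in% metrics) vals["CA"] <- n * cs^2
  if ("NP" %in% metrics) {
    vals["NP"] <- mask_components(window == code, config$connectivity)$count
  }
  need_faces <- any(c("TE", "LSI") %in% metrics)
  if (need_faces) {
    internal <- edge_faces(window, code, count_boundary = FALSE)
    cls <- window == code
    nr <- nrow(cls)
    nc <- ncol(cls)
    bnd <- sum(cls[1L, ]) + sum(cls[nr, ]) + sum(cls[, 1L]) + sum(cls[, nc])
    if ("TE" %in% metrics) {
      vals["TE"] <- (internal + if (config$count_boundary) bnd else 0L) * cs
    }
    if ("LSI" %in% metrics) {
      vals["LSI"] <- (internal + bnd) / min_edge_faces(n)
    }
  }
  if (any(c("TCA", "NDCA") %in% metrics)) {
    core <- core_mask(window, code, config$core_neighborhood)
    if ("TCA" %in% metrics) vals["TCA"] <- sum(core) * cs^2
    if ("NDCA" %in% metrics) {
      vals["NDCA"] <- mask_components(core, config$connectivity)$count
    }
  }
  list(values = vals, missing = miss)
}

#' Compute the six class-level metrics for one landscape window
#'
#' One record per requested land class and metric.  Water and ocean
#' classes are never emitted; NoData cells participate only as "different"
#' neighbours.  Absent classes follow the catalog's absence semantics:
#' zero for CA, NP, TE, TCA and NDCA, missing for LSI.
#'
#' @param window Integer class-code matrix.
#' @param catalog Class catalog (see [lulc_catalog()]); used to restrict
#'   records to land classes.
#' @param config A [metric_config()].
#' @param classes Class codes to compute; defaults to all land classes in
#'   the catalog.  Non-land codes are dropped.
#' @param metrics Subset of metric names to compute (default all six).
#' @return Tibble with columns `class`, `metric`, `value`, `missing`.
#' @export
compute_landscape_metrics <- function(window, catalog = lulc_catalog(),
                                      config = metric_config(),
                                      classes = NULL,
                                      metrics = metric_catalog()$metric) {
  lp_validate(all(metrics %in% metric_catalog()$metric),
              "unknown metric name(s): ",
              paste(setdiff(metrics, metric_catalog()$metric), collapse = ", "))
  classes <- classes %||% land_codes(catalog)
  classes <- intersect(as.integer(classes), land_codes(catalog))
  if (length(classes) == 0L) {
    return(tibble::tibble(class = integer(), metric = character(),
                          value = numeric(), missing = logical()))
  }
  out <- lapply(classes, function(code) {
    mv <- metric_values(window, code, config, metrics)
    tibble::tibble(class = code, metric = metrics,
                   value = unname(mv$values), missing = unname(mv$missing))
  })
  dplyr::bind_rows(out)
}

#' Apply absence-to-zero rules to metric records
#'
#' Missing records of metrics whose value is genuinely zero when a class
#' is absent (CA, NP, TE, TCA, NDCA) become zero with the missing flag
#' cleared; metrics that are undefined for absent classes (LSI) stay
#' missing.
#'
#' @param records Tibble with at least `metric`, `value`, `missing`.
#' @param catalog A [metric_catalog()].
#' @return The records with the rule applied.
#' @export
apply_absence_rules <- function(records, catalog = metric_catalog()) {
  unknown <- setdiff(unique(records$metric), catalog$metric)
  if (length(unknown) > 0) {
    lp_stop("unknown metric name(s): ", paste(unknown, collapse = ", "))
  }
  zero_metrics <- catalog$metric[catalog$absent_semantics == "zero"]
  fix <- records$missing & records$metric %in% zero_metrics
  records$value[fix] <- 0
  records$missing[fix] <- FALSE
  records
}
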
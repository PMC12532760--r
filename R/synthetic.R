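# Neutral-landscape-model generator of yearly categorical land-cover
# series.  A single seeded RNG stream is advanced in a fixed, documented
# order: ocean mask, percolation map, cluster-to-class assignment
# tie-breaks, gap filling, then operators by year and list position.

# contiguous, edge-anchored ocean blob grown to n_target cells (Eden growth)
grow_ocean_mask <- function(nr, nc, n_target) {
  mask <- matrix(FALSE, nr, nc)
  if (n_target <= 0) return(mask)
  edge <- unique(c(
    seq_len(nr),                      # left column
    seq_len(nr) + (nc - 1L) * nr,     # right column
    (seq_len(nc) - 1L) * nr + 1L,     # top row
    (seq_len(nc) - 1L) * nr + nr      # bottom row
  ))
  start <- resample(edge, 1L)
  mask[start] <- TRUE
  n <- 1L
  frontier <- neighbors4(start, nr, nc)
  while (n < n_target) {
    frontier <- unique(frontier[!mask[frontier]])
    if (length(frontier) == 0L) break
    k <- min(n_target - n, max(1L, ceiling(length(frontier) * 0.5)))
    picked <- resample(frontier, k)
    mask[picked] <- TRUE
    n <- n + k
    frontier <- c(frontier[!mask[frontier]], neighbors4(picked, nr, nc))
  }
  mask
}

# modified-random-clusters initial map; expects the RNG stream to be seeded
initial_map_impl <- function(scenario) {
  nr <- scenario$grid_rows
  nc <- scenario$grid_cols
  codes <- as.integer(scenario$classes$code)
  props <- scenario$classes$proportion
  n_total <- nr * nc
  ocean <- grow_ocean_mask(nr, nc, round(scenario$ocean_fraction * n_total))
  land_idx <- which(!ocean)
  lp_validate(length(land_idx) >= length(codes),
              "grid too small: fewer land cells than classes")

  grid <- matrix(scenario$ocean_code, nr, nc)
  # degenerate composition: a single class fills all land directly
  active <- which(props > 0)
  if (length(active) == 1L) {
    grid[land_idx] <- codes[active]
    storage.mode(grid) <- "integer"
    return(list(grid = grid, ocean = ocean))
  }

  # 1) percolation map on land cells
  filled <- matrix(FALSE, nr, nc)
  filled[land_idx] <- runif(length(land_idx)) < scenario$cluster_density

  # 2) 8-connected clusters, assigned largest-first to the class with the
  #    largest remaining target deficit
  assigned <- matrix(0L, nr, nc)
  comp <- mask_components(filled, connectivity = 8L)
  if (comp$count > 0L) {
    sizes <- tabulate(comp$labels[filled], nbins = comp$count)
    # distribute the filled cells (not all land cells) in target proportions;
    # the gap-filling stage then roughly preserves these shares
    targets <- props * sum(sizes)
    got <- numeric(length(codes))
    lab_of <- comp$labels
    for (lab in order(sizes, decreasing = TRUE)) {
      cls <- which.max(targets - got)
      cells <- which(lab_of == lab)
      assigned[cells] <- codes[cls]
      got[cls] <- got[cls] + sizes[lab]
    }
  }

  # 3) unassigned land cells take the modal class of their assigned
  #    8-neighbours (seeded random tie-break), iterating outwards
  shifts <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L),
                 c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L))
  repeat {
    todo <- which(assigned == 0L & !ocean)
    if (length(todo) == 0L) break
    counts <- matrix(0L, length(todo), length(codes))
    for (s in shifts) {
      for (ci in seq_along(codes)) {
        nb <- shift_mask(assigned == codes[ci], s[1], s[2])
        counts[, ci] <- counts[, ci] + nb[todo]
      }
    }
    has_nb <- rowSums(counts) > 0L
    if (!any(has_nb)) {
      # isolated remainder (e.g. no percolation cluster nearby at all):
      # draw from the target composition
      assigned[todo] <- resample(rep(codes, ceiling(length(todo) * props) + 1L),
                                 length(todo))
      break
    }
    pick <- max.col(counts[has_nb, , drop = FALSE], ties.method = "random")
    assigned[todo[has_nb]] <- codes[pick]
  }

  grid[land_idx] <- assigned[land_idx]
  storage.mode(grid) <- "integer"
  list(grid = grid, ocean = ocean)
}

#' Generate the initial synthetic land-cover map
#'
#' Modified-random-clusters neutral landscape model: a contiguous,
#' edge-anchored ocean blob is grown to `ocean_fraction` of the grid;
#' remaining land cells receive a percolation map at `cluster_density`
#' whose 8-connected clusters are assigned largest-first to classes by
#' greedy filling of the target proportions; cells outside clusters take
#' the modal class of their nearest assigned neighbours.
#'
#' @param scenario An [lulc_scenario()].
#' @param seed Integer seed (defaults to the scenario's).
#' @return Integer matrix of class codes; ocean cells carry the scenario's
#'   ocean code.
#' @export
generate_initial_map <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "lulc_scenario"))
  set.seed(seed)
  initial_map_impl(scenario)$grid
}

# ---- change operators ------------------------------------------------------

empty_log <- function() {
  tibble::tibble(
    year = integer(), row = integer(), col = integer(),
    from_class = integer(), to_class = integer(), operator = character()
  )
}

log_rows <- function(idx, nr, from, to, operator) {
  tibble::tibble(
    year = NA_integer_, row = idx_row(idx, nr), col = idx_col(idx, nr),
    from_class = as.integer(from), to_class = as.integer(to),
    operator = operator
  )
}

# expects seeded RNG; `protected` = codes never modified (ocean, NoData)
apply_op_impl <- function(grid, op, protected) {
  nr <- nrow(grid)
  src <- as.integer(op$source)
  tgt <- as.integer(op$target %||% NA_integer_)
  rate <- as.integer(op$rate)
  logs <- list()
  if (rate == 0L) return(list(grid = grid, log = empty_log()))
  prot_mask <- matrix(grid %in% protected, nr, ncol(grid))

  if (op$kind == "expand") {
    remaining <- rate
    repeat {
      src_mask <- grid == src
      cand <- which(dilate4(src_mask) & !src_mask & !prot_mask)
      if (remaining == 0L || length(cand) == 0L) break
      picked <- resample(cand, min(remaining, length(cand)))
      logs[[length(logs) + 1L]] <- log_rows(picked, nr, grid[picked], src, "expand")
      grid[picked] <- src
      remaining <- remaining - length(picked)
    }
  } else if (op$kind == "contract") {
    remaining <- rate
    repeat {
      src_mask <- grid == src
      cand <- which(src_mask & dilate4(!src_mask))
      if (remaining == 0L || length(cand) == 0L) break
      picked <- resample(cand, min(remaining, length(cand)))
      logs[[length(logs) + 1L]] <- log_rows(picked, nr, src, tgt, "contract")
      grid[picked] <- tgt
      remaining <- remaining - length(picked)
    }
  } else if (op$kind == "fragment") {
    remaining <- rate
    while (remaining > 0L) {
      src_mask <- grid == src
      n_comp <- mask_components(src_mask, 8L)$count
      if (n_comp == 0L) break
      # articulation candidates: source cells with >= 2 source neighbours
      nb_cnt <- Reduce(`+`, lapply(
        list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
             c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)),
        function(s) shift_mask(src_mask, s[1], s[2])
      ))
      cand <- which(src_mask & nb_cnt >= 2L)
      cand <- resample(cand, length(cand))
      cut_cell <- NA_integer_
      for (cell in cand) {
        grid[cell] <- tgt
        if (mask_components(grid == src, 8L)$count > n_comp) {
          cut_cell <- cell
          break
        }
        grid[cell] <- src
      }
      if (is.na(cut_cell)) {
        # no articulation cell exists: fall back to one boundary cell
        bnd <- which(src_mask & dilate4(!src_mask))
        if (length(bnd) == 0L) break
        cut_cell <- resample(bnd, 1L)
        grid[cut_cell] <- tgt
      }
      logs[[length(logs) + 1L]] <- log_rows(cut_cell, nr, src, tgt, "fragment")
      remaining <- remaining - 1L
    }
  } else if (op$kind == "convert") {
    lab <- label_patches(grid, src, connectivity = 8L)
    if (lab$count > 0L) {
      sizes <- tabulate(lab$labels[lab$labels > 0L], nbins = lab$count)
      budget <- rate
      for (p in order(sizes)) {
        if (sizes[p] > budget) break
        cells <- which(lab$labels == p)
        logs[[length(logs) + 1L]] <- log_rows(cells, nr, src, tgt, "convert")
        grid[cells] <- tgt
        budget <- budget - sizes[p]
      }
    }
  } else {
    lp_stop("unknown operator kind: ", op$kind, class = "lp_validation_error")
  }
  log <- if (length(logs) > 0) dplyr::bind_rows(logs) else empty_log()
  list(grid = grid, log = log)
}

#' Apply one change operator to a categorical grid
#'
#' Four operator kinds model the elementary processes of land-cover
#' change: `expand` converts up to `rate` land cells 4-adjacent to the
#' source class into the source class; `contract` converts up to `rate`
#' source boundary cells to the target class; `fragment` removes up to
#' `rate` articulation/corridor cells (cells whose removal increases the
#' 8-connected patch count of the source class), falling back to boundary
#' cells when none exist; `convert` relabels whole smallest source patches
#' to the target while their cumulative size fits within `rate`.  Ocean
#' and NoData cells are never modified.
#'
#' @param grid Integer class-code matrix.
#' @param op Operator spec: list with `kind`, `source`, `target`, `rate`.
#' @param protected Integer codes never modified (default ocean 0 and
#'   NoData 255).
#' @param seed Optional integer; when given, seeds the RNG first.  Leave
#'   `NULL` inside a larger seeded computation.
#' @return List with the new `grid` and a `log` tibble (columns `year`
#'   (NA here), `row`, `col`, `from_class`, `to_class`, `operator`).
#' @export
apply_change_operator <- function(grid, op, protected = c(0L, 255L), seed = NULL) {
  lp_validate(!is.null(op$kind) &&
                op$kind %in% c("expand", "contract", "fragment", "convert"),
              "unknown operator kind: ", op$kind %||% "<missing>")
  lp_validate(is_count(op$rate %||% -1), "operator rate must be a non-negative integer")
  if (op$kind != "expand") {
    lp_validate(!is.null(op$target) && !(op$target %in% protected),
                "operator target must be a modifiable land class")
    if (op$rate > 0) {
      lp_validate(any(grid == op$source),
                  "source class ", op$source, " absent from grid")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  apply_op_impl(grid, op, protected)
}

#' Generate a synthetic yearly land-cover series with its change log
#'
#' Year one comes from [generate_initial_map()]; every subsequent year is
#' produced by applying that year's operators in listed order.  The ocean
#' mask is constant across years and the returned log records every
#' changed cell, so replaying the log on the first year reproduces the
#' whole series exactly.
#'
#' @param scenario An [lulc_scenario()].
#' @return List with `series` (an [lulc_series()]) and `log` (tibble:
#'   `year`, `row`, `col`, `from_class`, `to_class`, `operator`).  The
#'   `year` of a log row is the year whose map the change produced.
#' @export
generate_series <- function(scenario) {
  stopifnot(inherits(scenario, "lulc_scenario"))
  set.seed(scenario$seed)
  protected <- c(scenario$ocean_code, scenario$nodata)
  grid <- initial_map_impl(scenario)$grid
  years <- scenario$years
  grids <- vector("list", length(years))
  grids[[1]] <- grid
  logs <- list()
  for (t in seq_along(years)[-1]) {
    yr <- years[t]
    for (op in scenario$operators) {
      rng <- op$years %||% range(years)
      if (yr < rng[1] || yr > tail(rng, 1)) next
      res <- apply_op_impl(grid, op, protected)
      grid <- res$grid
      if (nrow(res$log) > 0) {
        res$log$year <- yr
        logs[[length(logs) + 1L]] <- res$log
      }
    }
    grids[[t]] <- grid
  }
  series <- lulc_series(
    grids = grids, years = years, cell_size_km = scenario$cell_size_km,
    catalog = scenario_catalog(scenario), nodata = scenario$nodata
  )
  log <- if (length(logs) > 0) dplyr::bind_rows(logs) else empty_log()
  list(series = series, log = log)
}

#' Replay a change log on an initial map
#'
#' Applies the logged cell changes year by year, reproducing the series
#' they came from.
#'
#' @param initial Integer matrix: the first year's map.
#' @param log Change-log tibble as returned by [generate_series()].
#' @param years Integer years of the full series (first = the initial map).
#' @return List of matrices, one per year.
#' @export
replay_change_log <- function(initial, log, years) {
  grids <- vector("list", length(years))
  names(grids) <- years
  grids[[1]] <- initial
  grid <- initial
  nr <- nrow(initial)
  for (t in seq_along(years)[-1]) {
    rows <- log[log$year == years[t], , drop = FALSE]
    if (nrow(rows) > 0) {
      grid[(rows$col - 1L) * nr + rows$row] <- rows$to_class
    }
    grids[[t]] <- grid
  }
  grids
}
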
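# Brute-force oracles, deliberately independent of the package internals:
# breadth-first search for patches and cores, per-cell face enumeration
# for edges, and exhaustive polyomino enumeration for minimum perimeters.

oracle_neighbors <- function(r, c, nr, nc, connectivity) {
  d <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8) {
    d <- c(d, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  }
  out <- list()
  for (dd in d) {
    rr <- r + dd[1]
    cc <- c + dd[2]
    if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
      out[[length(out) + 1]] <- c(rr, cc)
    }
  }
  out
}

# BFS connected-component count of a logical mask
oracle_components <- function(mask, connectivity) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (!mask[r, c] || seen[r, c]) next
      count <- count + 1
      queue <- list(c(r, c))
      seen[r, c] <- TRUE
      while (length(queue) > 0) {
        cell <- queue[[1]]
        queue <- queue[-1]
        for (nb in oracle_neighbors(cell[1], cell[2], nr, nc, connectivity)) {
          if (mask[nb[1], nb[2]] && !seen[nb[1], nb[2]]) {
            seen[nb[1], nb[2]] <- TRUE
            queue[[length(queue) + 1]] <- nb
          }
        }
      }
    }
  }
  count
}

oracle_np <- function(window, class_code, connectivity = 8) {
  oracle_components(window == class_code, connectivity)
}

# faces counted from the class side, one per cell face
oracle_edge_faces <- function(window, class_code, count_boundary = FALSE) {
  nr <- nrow(window)
  nc <- ncol(window)
  faces <- 0
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (window[r, c] != class_code) next
      for (dd in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + dd[1]
        cc <- c + dd[2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) {
          if (count_boundary) faces <- faces + 1
        } else if (window[rr, cc] != class_code) {
          faces <- faces + 1
        }
      }
    }
  }
  faces
}

oracle_core_mask <- function(window, class_code, neighborhood = 4) {
  nr <- nrow(window)
  nc <- ncol(window)
  core <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (window[r, c] != class_code) next
      nbs <- oracle_neighbors(r, c, nr, nc, neighborhood)
      full <- if (neighborhood == 4) 4 else 8
      if (length(nbs) < full) next  # window border: missing neighbour disqualifies
      ok <- all(vapply(nbs, function(nb) window[nb[1], nb[2]] == class_code, TRUE))
      core[r, c] <- ok
    }
  }
  core
}

oracle_tca <- function(window, class_code, cell_size = 1, neighborhood = 4) {
  sum(oracle_core_mask(window, class_code, neighborhood)) * cell_size^2
}

oracle_ndca <- function(window, class_code, connectivity = 8, neighborhood = 4) {
  oracle_components(oracle_core_mask(window, class_code, neighborhood), connectivity)
}

oracle_lsi <- function(window, class_code, min_faces_fun) {
  n <- sum(window == class_code)
  if (n == 0) return(NA_real_)
  oracle_edge_faces(window, class_code, count_boundary = TRUE) / min_faces_fun(n)
}

# ---- exhaustive polyomino search -------------------------------------------

poly_perimeter <- function(cells) {
  key <- paste(cells[, 1], cells[, 2])
  per <- 0
  for (i in seq_len(nrow(cells))) {
    for (dd in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      nb <- paste(cells[i, 1] + dd[1], cells[i, 2] + dd[2])
      if (!(nb %in% key)) per <- per + 1
    }
  }
  per
}

poly_canonical <- function(cells) {
  forms <- list(
    cells,
    cbind(cells[, 1], -cells[, 2]),
    cbind(-cells[, 1], cells[, 2]),
    cbind(-cells[, 1], -cells[, 2]),
    cells[, 2:1, drop = FALSE],
    cbind(cells[, 2], -cells[, 1]),
    cbind(-cells[, 2], cells[, 1]),
    cbind(-cells[, 2], -cells[, 1])
  )
  keys <- vapply(forms, function(f) {
    f[, 1] <- f[, 1] - min(f[, 1])
    f[, 2] <- f[, 2] - min(f[, 2])
    ord <- order(f[, 1], f[, 2])
    paste(f[ord, 1], f[ord, 2], sep = ",", collapse = ";")
  }, "")
  min(keys)
}

# all free polyominoes of sizes 1..n_max, grown cell by cell with
# canonical-form deduplication; returns min perimeter per size
oracle_min_perimeters <- function(n_max) {
  out <- numeric(n_max)
  polys <- list(matrix(c(1, 1), 1, 2))
  out[1] <- 4
  for (n in seq_len(n_max - 1) + 1) {
    nxt <- new.env(parent = emptyenv())
    for (p in polys) {
      key <- paste(p[, 1], p[, 2])
      for (i in seq_len(nrow(p))) {
        for (dd in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          cand <- c(p[i, 1] + dd[1], p[i, 2] + dd[2])
          if (paste(cand[1], cand[2]) %in% key) next
          q <- rbind(p, cand)
          ck <- poly_canonical(q)
          if (!exists(ck, envir = nxt, inherits = FALSE)) assign(ck, q, envir = nxt)
        }
      }
    }
    polys <- as.list(nxt)
    out[n] <- min(vapply(polys, poly_perimeter, 0))
  }
  out
}

# seeded random categorical windows with a mild clustered texture
random_window <- function(nr = 12, nc = 12, n_classes = 4) {
  codes <- seq_len(n_classes)
  w <- matrix(sample(codes, nr * nc, replace = TRUE), nr, nc)
  # a couple of random rectangles to create patches larger than one cell
  for (k in seq_len(3)) {
    r <- sort(sample(nr, 2))
    c <- sort(sample(nc, 2))
    w[r[1]:r[2], c[1]:c[2]] <- sample(codes, 1)
  }
  storage.mode(w) <- "integer"
  w
}
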
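`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() treats a length-1 numeric vector as 1:x; this never does.
resample <- function(x, k) x[sample.int(length(x), k)]

lp_stop <- function(..., class = "lp_error") {
  stop(structure(
    class = c(class, "lp_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

lp_validate <- function(ok, ...) {
  if (!ok) lp_stop(..., class = "lp_validation_error")
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && abs(x - round(x)) < 1e-9
}

# linear index helpers for an nr x nc matrix (column-major, as R stores it)
idx_row <- function(idx, nr) ((idx - 1L) %% nr) + 1L
idx_col <- function(idx, nr) ((idx - 1L) %/% nr) + 1L

# 4-neighbours of linear indices, respecting the matrix boundary
neighbors4 <- function(idx, nr, nc) {
  r <- idx_row(idx, nr)
  c <- idx_col(idx, nr)
  out <- c(
    idx[r > 1L] - 1L,
    idx[r < nr] + 1L,
    idx[c > 1L] - nr,
    idx[c < nc] + nr
  )
  out
}

# logical matrix shifted by (dr, dc), vacated cells filled with FALSE
shift_mask <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  sr <- max(1L, 1L + dr):min(nr, nr + dr)
  sc <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(sr) < 1L || length(sc) < 1L) return(out)
  out[sr, sc] <- m[sr - dr, sc - dc, drop = FALSE]
  out
}

# binary dilation of a logical matrix by the 4-neighbourhood
dilate4 <- function(m) {
  m | shift_mask(m, 1L, 0L) | shift_mask(m, -1L, 0L) |
    shift_mask(m, 0L, 1L) | shift_mask(m, 0L, -1L)
}
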
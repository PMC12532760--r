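# Shared fixtures built in code.

# plus-pentomino of `code` centred in a 5x5 window of background 99
pentomino_window <- function(code = 44L, bg = 99L) {
  w <- matrix(bg, 5, 5)
  w[2:4, 3] <- code
  w[3, 2] <- code
  w[3, 4] <- code
  storage.mode(w) <- "integer"
  w
}

# two 3x3 blocks joined by a 1-cell-wide, 3-cell corridor
dumbbell_window <- function(code = 44L, bg = 99L) {
  w <- matrix(bg, 5, 9)
  w[2:4, 1:3] <- code
  w[2:4, 7:9] <- code
  w[3, 4:6] <- code
  storage.mode(w) <- "integer"
  w
}

# catalog in which 99 is a second land class so pentomino/dumbbell windows
# validate; 0 = ocean
toy_catalog <- function() {
  data.frame(
    code = c(44L, 99L, 0L),
    name = c("forest", "other", "ocean"),
    role = c("land", "land", "ocean")
  )
}

two_class_scenario <- function(nr = 200, nc = 200, density = 0.4, seed = 7,
                               p = c(0.7, 0.3), ocean = 0) {
  lulc_scenario(
    nr, nc,
    classes = data.frame(code = c(1L, 2L), name = c("a", "b"), proportion = p),
    ocean_fraction = ocean, cluster_density = density,
    years = 2000, seed = seed
  )
}

# one-year series from a bare matrix
matrix_series <- function(mat, catalog = toy_catalog(), year = 2000,
                          cell_size = 1) {
  lulc_series(list(mat), years = year, cell_size_km = cell_size,
              catalog = catalog)
}

expect_no_mismatch <- function(n_mismatch, label) {
  expect_equal(n_mismatch, 0, label = label)
}
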
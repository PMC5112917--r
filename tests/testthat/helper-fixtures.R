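# Shared fixture builders. All fixtures are generated in code.

# A small grid whose cell values are a known plane of latitude/longitude,
# handy for closed-form extraction checks.
plane_grid <- function(nr = 10, nc = 12, origin_lon = -100, origin_lat = 48,
                       cell_size = 0.5, a = 5, b_lat = -2, b_lon = 0.5) {
  g <- iso_grid(matrix(0, nr, nc), origin_lon, origin_lat, cell_size)
  lats <- origin_lat - (seq_len(nr) - 0.5) * cell_size
  lons <- origin_lon + (seq_len(nc) - 0.5) * cell_size
  g$values <- outer(lats, lons, function(la, lo) a + b_lat * la + b_lon * lo)
  g
}

constant_grid <- function(value, nr = 5, nc = 5, origin_lon = -100,
                          origin_lat = 45, cell_size = 1) {
  iso_grid(matrix(value, nr, nc), origin_lon, origin_lat, cell_size)
}

# Minimal feather CSV on disk; returns the path.
write_feather_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

# Small bird table drawn around a feather isoscape: each bird sampled at a
# random cell centre with observation noise `sigma`.
birds_on_grid <- function(grid, n, sigma, seed = 1) {
  set.seed(seed)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  ri <- sample(nr, n, replace = TRUE)
  ci <- sample(nc, n, replace = TRUE)
  lat <- grid$origin_lat - (ri - 0.5) * grid$cell_size
  lon <- grid$origin_lon + (ci - 0.5) * grid$cell_size
  mu <- grid$values[cbind(ri, ci)]
  tibble::tibble(
    bird_id = sprintf("b%03d", seq_len(n)),
    lat = lat, lon = lon,
    d2h = mu + stats::rnorm(n, 0, sigma)
  )
}
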
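# Shared toy fixtures, all built in code.

toy_grid <- function(n_rows = 4, n_cols = n_rows, cell = 0.25,
                     west = 0, north = 1) {
  mastergrid(cell, west, north, n_rows, n_cols)
}

square_ring <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

# a raster with the given values (filled column-major) on a toy grid
toy_raster <- function(values, n_rows = 4, n_cols = n_rows, cell = 0.25,
                       kind = "continuous", west = 0, north = 1) {
  g <- toy_grid(n_rows, n_cols, cell, west, north)
  grid_raster(g, matrix(values, n_rows, n_cols), kind)
}

# independent haversine, spelled out from the formula
haversine_oracle <- function(lon1, lat1, lon2, lat2, R = 6371007.181) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}
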
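#' Geographic mastergrid definition
#'
#' A mastergrid is the common lat/lon grid frame that every layer in an
#' analysis shares: a cell size in decimal degrees, the top-left corner of the
#' grid, its dimensions, and the no-data sentinel. Grids are north-up with
#' half-open cells: cell (r, c) covers
#' `[origin_lon + (c-1)*s, origin_lon + c*s)` in longitude and
#' `(origin_lat - r*s, origin_lat - (r-1)*s]` in latitude.
#' Origins are always an integer number of cells from the global anchor
#' (-180, 90), so independently defined grids at the same resolution align.
#'
#' @param cell_size Cell edge in decimal degrees (> 0).
#' @param origin_lon,origin_lat Top-left corner, decimal degrees; must be
#'   snapped to the (-180, 90) anchor.
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param nodata No-data sentinel stored with the grid (default -99999).
#' @return A `mastergrid` object.
#' @seealso [define_mastergrid()] to build a snapped grid from a bounding box.
#' @export
mastergrid <- function(cell_size, origin_lon, origin_lat, n_rows, n_cols,
                       nodata = -99999) {
  stopifnot(is.numeric(cell_size), length(cell_size) == 1L, cell_size > 0)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) {
    stop("mastergrid dimensions must be positive", call. = FALSE)
  }
  g <- structure(
    list(cell_size = as.numeric(cell_size),
         origin_lon = as.numeric(origin_lon),
         origin_lat = as.numeric(origin_lat),
         n_rows = n_rows, n_cols = n_cols,
         nodata = as.numeric(nodata)),
    class = "mastergrid"
  )
  if (!is_snapped(origin_lon, cell_size, -180) ||
      !is_snapped(origin_lat, cell_size, 90, descending = TRUE)) {
    stop("mastergrid origin is not snapped to the (-180, 90) anchor",
         call. = FALSE)
  }
  ext <- grid_extent(g)
  if (ext["west"] < -180 - 1e-9 || ext["east"] > 180 + 1e-9 ||
      ext["south"] < -90 - 1e-9 || ext["north"] > 90 + 1e-9) {
    stop("mastergrid extent falls outside the globe", call. = FALSE)
  }
  g
}

# snapped <=> value lies an integer number of steps from the anchor
is_snapped <- function(value, step, anchor, descending = FALSE, tol = 1e-7) {
  k <- if (descending) (anchor - value) / step else (value - anchor) / step
  abs(k - round(k)) < tol
}

#' Define a snapped mastergrid covering a bounding box
#'
#' Expands `bounds` outward to the nearest cell edges measured from the global
#' anchor (-180, 90) and returns the smallest snapped grid that fully covers
#' the box. Applying it to an already-snapped box is the identity.
#'
#' @param bounds Numeric vector `c(west, south, east, north)` in decimal
#'   degrees, non-degenerate and inside the globe.
#' @param cell_size Cell edge in decimal degrees (e.g. 3 arc-seconds is
#'   `3/3600 = 0.00083333333`).
#' @param nodata No-data sentinel (default -99999).
#' @return A `mastergrid` covering `bounds`.
#' @examples
#' define_mastergrid(c(0.1, 0.1, 0.9, 0.9), 0.25)
#' @export
define_mastergrid <- function(bounds, cell_size, nodata = -99999) {
  stopifnot(is.numeric(bounds), length(bounds) == 4L)
  names(bounds) <- c("west", "south", "east", "north")
  if (bounds["east"] <= bounds["west"] || bounds["north"] <= bounds["south"]) {
    stop("bounds are inverted or degenerate: need west < east and south < north",
         call. = FALSE)
  }
  if (bounds["west"] < -180 || bounds["east"] > 180 ||
      bounds["south"] < -90 || bounds["north"] > 90) {
    stop("bounds fall outside [-180, 180] x [-90, 90]", call. = FALSE)
  }
  s <- cell_size
  # integer cell offsets from the anchor, rounded with a small tolerance so
  # boxes already on cell edges are fixed points of the snapping
  tol <- 1e-9
  c_w <- floor((bounds["west"] + 180) / s + tol)
  c_e <- ceiling((bounds["east"] + 180) / s - tol)
  r_n <- floor((90 - bounds["north"]) / s + tol)
  r_s <- ceiling((90 - bounds["south"]) / s - tol)
  mastergrid(cell_size = s,
             origin_lon = -180 + c_w * s,
             origin_lat = 90 - r_n * s,
             n_rows = as.integer(r_s - r_n),
             n_cols = as.integer(c_e - c_w),
             nodata = nodata)
}

#' @export
print.mastergrid <- function(x, ...) {
  ext <- grid_extent(x)
  cat(sprintf("<mastergrid> %d x %d cells of %.10g deg\n",
              x$n_rows, x$n_cols, x$cell_size))
  cat(sprintf("  extent: lon [%.6g, %.6g], lat [%.6g, %.6g]; nodata %g\n",
              ext["west"], ext["east"], ext["south"], ext["north"], x$nodata))
  invisible(x)
}

#' Grid extent
#'
#' @param grid A `mastergrid`.
#' @return Named numeric vector `c(west, south, east, north)`.
#' @export
grid_extent <- function(grid) {
  c(west = grid$origin_lon,
    south = grid$origin_lat - grid$n_rows * grid$cell_size,
    east = grid$origin_lon + grid$n_cols * grid$cell_size,
    north = grid$origin_lat)
}

#' Cell-centre coordinates
#'
#' Longitudes of the column centres and latitudes of the row centres.
#'
#' @param grid A `mastergrid`.
#' @return Numeric vector of length `n_cols` (resp. `n_rows`).
#' @export
cell_lon <- function(grid) {
  grid$origin_lon + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
}

#' @rdname cell_lon
#' @export
cell_lat <- function(grid) {
  grid$origin_lat - (seq_len(grid$n_rows) - 0.5) * grid$cell_size
}

same_grid <- function(a, b, tol = 1e-9) {
  abs(a$cell_size - b$cell_size) < tol &&
    abs(a$origin_lon - b$origin_lon) < tol &&
    abs(a$origin_lat - b$origin_lat) < tol &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

check_same_grid <- function(a, b, what = "rasters") {
  if (!same_grid(a, b)) {
    stop(sprintf("%s are not co-registered on the same mastergrid", what),
         call. = FALSE)
  }
  invisible(TRUE)
}
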
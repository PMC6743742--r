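#' Rasterise administrative unit polygons
#'
#' Burns unit IDs into a categorical raster by centre-point sampling: each
#' cell receives the ID of the polygon containing its centre; cells whose
#' centre lies in no polygon are no-data. Where overlapping polygons cover a
#' common cell centre the lowest ID wins (deterministic and independent of
#' input order) and a warning reports the collision.
#'
#' @param polygons A [polygon_frame()] with positive unique IDs.
#' @param grid Target [mastergrid()].
#' @return A categorical `grid_raster` of unit IDs (an admin-ID raster).
#' @export
rasterize_admin_units <- function(polygons, grid) {
  stopifnot(inherits(grid, "mastergrid"))
  if (!all(c("id", "geometry") %in% names(polygons))) {
    stop("polygons must carry 'id' and 'geometry' columns", call. = FALSE)
  }
  if (nrow(polygons) && (any(polygons$id <= 0) || anyDuplicated(polygons$id))) {
    stop("polygon IDs must be positive and unique", call. = FALSE)
  }
  vals <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  if (nrow(polygons) == 0L) return(grid_raster(grid, vals, "categorical"))
  lon <- cell_lon(grid); lat <- cell_lat(grid)
  px <- rep(lon, each = grid$n_rows)
  py <- rep(lat, times = grid$n_cols)
  overlap <- FALSE
  # visit polygons in decreasing ID order so the lowest ID is written last
  for (i in order(polygons$id, decreasing = TRUE)) {
    ring <- polygons$geometry[[i]]
    inside <- point_in_ring(px, py, ring)
    if (any(inside & !is.na(vals))) overlap <- TRUE
    vals[inside] <- polygons$id[i]
  }
  if (overlap) {
    warning("overlapping polygons cover common cell centres; lowest ID kept",
            call. = FALSE)
  }
  grid_raster(grid, vals, "categorical")
}

#' Integrate inland waterbodies into an admin-ID raster
#'
#' Administrative boundaries take priority over water: cells that already
#' carry a unit ID keep it even where the water mask is 1. Cells with no unit
#' ID that are flagged as water become the reserved water code; everything
#' else is unchanged.
#'
#' @param admin Admin-ID `grid_raster` (categorical).
#' @param water Co-registered binary `grid_raster` (1 = water).
#' @param water_code Reserved code for inland water; must not collide with a
#'   unit ID (default 9999).
#' @return The adjusted admin-ID raster, with the water code recorded in
#'   attribute `"water_code"`.
#' @export
integrate_waterbodies <- function(admin, water, water_code = 9999) {
  check_same_grid(admin$grid, water$grid)
  if (water$kind != "binary") stop("water mask must be binary", call. = FALSE)
  if (water_code %in% admin$values) {
    stop("water code collides with an existing unit ID", call. = FALSE)
  }
  vals <- admin$values
  fill <- is.na(vals) & !is.na(water$values) & water$values == 1
  vals[fill] <- water_code
  out <- grid_raster(admin$grid, vals, "categorical")
  attr(out, "water_code") <- water_code
  out
}

# unit IDs present in an admin raster, excluding the reserved water code
admin_unit_ids <- function(admin) {
  wc <- attr(admin, "water_code")
  ids <- sort(unique(admin$values[!is.na(admin$values)]))
  if (!is.null(wc)) ids <- setdiff(ids, wc)
  ids
}
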
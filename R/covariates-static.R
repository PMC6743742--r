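#' Spherical Earth model
#'
#' All metric computations use a spherical approximation of the Earth. The
#' default radius is the authalic sphere (equal surface area to the WGS84
#' ellipsoid), the natural choice when the quantity of interest is area.
#'
#' @param R Sphere radius in metres.
#' @return An `earth_model`.
#' @export
earth_model <- function(R = 6371007.181) {
  stopifnot(is.numeric(R), R > 0)
  structure(list(R = R), class = "earth_model")
}

#' Per-cell surface area of a lat/lon grid
#'
#' For a regularly spaced geographic grid on a sphere, the area of a cell
#' spanning longitudes of width `dl` (radians) between latitudes `phi_b` and
#' `phi_t` is `R^2 * dl * (sin(phi_t) - sin(phi_b))` - constant along each
#' row, shrinking towards the poles, and summing to `4*pi*R^2` over any full
#' global grid.
#'
#' @param grid A [mastergrid()].
#' @param earth An [earth_model()].
#' @return Continuous `grid_raster` of cell areas in square metres.
#' @export
pixel_area_grid <- function(grid, earth = earth_model()) {
  stopifnot(inherits(grid, "mastergrid"))
  s_rad <- grid$cell_size * pi / 180
  lat_top <- (grid$origin_lat - (seq_len(grid$n_rows) - 1) * grid$cell_size) * pi / 180
  row_area <- earth$R^2 * s_rad * (sin(lat_top) - sin(lat_top - s_rad))
  grid_raster(grid, matrix(row_area, grid$n_rows, grid$n_cols), "continuous")
}

#' Slope from a digital elevation model
#'
#' Horn's 3x3 finite-difference gradient with metric spacing derived from the
#' grid: east-west spacing `R*cos(lat)*dlon` per row, north-south spacing
#' `R*dlat`. Slope is `atan(|grad z|)` in degrees. Border cells and cells
#' adjacent to no-data are no-data (the stencil is undefined there).
#'
#' @param dem Continuous `grid_raster` of elevations in metres.
#' @param earth An [earth_model()].
#' @return Continuous `grid_raster` of slope in degrees.
#' @export
slope_from_dem <- function(dem, earth = earth_model()) {
  if (dem$kind != "continuous") stop("dem must be continuous", call. = FALSE)
  g <- dem$grid
  if (g$n_rows < 3 || g$n_cols < 3) {
    stop("slope needs a raster of at least 3 x 3 cells", call. = FALSE)
  }
  z <- dem$values
  nr <- g$n_rows; nc <- g$n_cols
  s_rad <- g$cell_size * pi / 180
  dy <- earth$R * s_rad
  dx <- earth$R * cos(cell_lat(g) * pi / 180) * s_rad   # per row
  out <- matrix(NA_real_, nr, nc)
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  z1 <- z[ri - 1, ci - 1]; z2 <- z[ri - 1, ci]; z3 <- z[ri - 1, ci + 1]
  z4 <- z[ri,     ci - 1];                      z6 <- z[ri,     ci + 1]
  z7 <- z[ri + 1, ci - 1]; z8 <- z[ri + 1, ci]; z9 <- z[ri + 1, ci + 1]
  dzdx <- ((z3 + 2 * z6 + z9) - (z1 + 2 * z4 + z7)) / (8 * dx[ri])
  dzdy <- ((z1 + 2 * z2 + z3) - (z7 + 2 * z8 + z9)) / (8 * dy)
  out[ri, ci] <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  out[is.na(z)] <- NA_real_   # input no-data propagates (Horn skips z5)
  grid_raster(g, out, "continuous")
}

#' Default nine-class land-cover aggregation
#'
#' A stand-in aggregation of detailed land-use sub-category codes into nine
#' broad classes (cropland, tree cover, grass/shrub, sparse vegetation,
#' wetland, built settlement, bare, water, snow/ice). Replace it with your
#' own table (`source_code`, `aggregate_code`, `label`) when the source
#' product defines a different legend.
#'
#' @return Tibble with columns `source_code`, `aggregate_code`, `label`.
#' @export
default_landcover_mapping <- function() {
  agg <- tibble::tribble(
    ~aggregate_code, ~label,
    1, "cropland",
    2, "tree cover",
    3, "grass/shrubland",
    4, "sparse vegetation",
    5, "wetland",
    6, "built settlement",
    7, "bare",
    8, "water",
    9, "snow/ice"
  )
  src <- tibble::tibble(
    source_code = c(10, 11, 12, 20, 30, 40,            # cropland mosaic codes
                    50, 60, 61, 62, 70, 80, 90, 100,   # forest codes
                    110, 120, 121, 122, 130,           # grass / shrub
                    140, 150, 152, 153,                # sparse
                    160, 170, 180,                     # flooded / wetland
                    190,                               # urban
                    200, 201, 202,                     # bare
                    210,                               # water
                    220),                              # permanent snow & ice
    aggregate_code = c(rep(1, 6), rep(2, 8), rep(3, 5), rep(4, 4),
                       rep(5, 3), 6, rep(7, 3), 8, 9)
  )
  dplyr::left_join(src, agg, by = "aggregate_code")
}

#' Reclassify a categorical raster
#'
#' Replaces detailed source codes with aggregate classes according to a
#' mapping table; no-data is preserved and the per-class cell histogram is
#' conserved (each aggregate count is the sum of its source-code counts).
#'
#' @param lc Categorical `grid_raster`.
#' @param mapping Tibble with columns `source_code`, `aggregate_code`
#'   (default [default_landcover_mapping()]). Every code observed in `lc`
#'   must be mapped.
#' @return Categorical `grid_raster` of aggregate classes.
#' @export
reclassify_landcover <- function(lc, mapping = default_landcover_mapping()) {
  observed <- unique(lc$values[!is.na(lc$values)])
  unmapped <- setdiff(observed, mapping$source_code)
  if (length(unmapped)) {
    stop("unmapped land-cover code(s): ",
         paste(sort(unmapped), collapse = ", "), call. = FALSE)
  }
  idx <- match(lc$values, mapping$source_code)
  vals <- matrix(mapping$aggregate_code[idx],
                 lc$grid$n_rows, lc$grid$n_cols)
  grid_raster(lc$grid, vals, "categorical")
}

#' Extract classes of a categorical raster as a binary/presence layer
#'
#' `binary` mode writes 1 where the cell value is in `classes` and 0 on every
#' other data cell; `presence` mode writes 1 on matching cells and no-data
#' elsewhere (the "single value" layer style).
#'
#' @param src Categorical (or binary) `grid_raster`.
#' @param classes Non-empty set of values to extract.
#' @param mode `"binary"` or `"presence"`.
#' @return Binary `grid_raster`.
#' @export
binary_extract <- function(src, classes, mode = c("binary", "presence")) {
  mode <- match.arg(mode)
  if (length(classes) == 0) stop("classes must be non-empty", call. = FALSE)
  v <- src$values
  hit <- !is.na(v) & v %in% classes
  out <- matrix(NA_real_, nrow(v), ncol(v))
  out[hit] <- 1
  if (mode == "binary") out[!is.na(v) & !hit] <- 0
  grid_raster(src$grid, out, "binary")
}

#' Great-circle distance to the nearest feature cell
#'
#' Haversine distance from each cell centre to the nearest centre of a
#' feature cell (value 1); feature cells get 0.
#'
#' @param feature Binary `grid_raster` with at least one feature cell.
#' @param earth An [earth_model()].
#' @return Continuous `grid_raster` of distances in metres.
#' @export
distance_to_feature <- function(feature, earth = earth_model()) {
  g <- feature$grid
  feat <- which(!is.na(feature$values) & feature$values == 1)
  if (length(feat) == 0L) {
    stop("distance_to_feature: no feature cells present", call. = FALSE)
  }
  lon <- cell_lon(g); lat <- cell_lat(g)
  fr <- ((feat - 1L) %% g$n_rows) + 1L
  fc <- ((feat - 1L) %/% g$n_rows) + 1L
  fpts <- cbind(lon[fc], lat[fr])
  all_pts <- cbind(rep(lon, each = g$n_rows), rep(lat, times = g$n_cols))
  out <- rep(Inf, nrow(all_pts))
  for (k in seq_len(nrow(fpts))) {
    out <- pmin(out, geosphere::distHaversine(all_pts, fpts[k, ], r = earth$R))
  }
  out[feat] <- 0
  grid_raster(g, matrix(out, g$n_rows, g$n_cols), "continuous")
}

#' Annualise monthly climate rasters
#'
#' Mean of the 12 monthly rasters for temperature-like variables, sum for
#' precipitation-like variables. A cell that is no-data in any month is
#' no-data in the annual layer.
#'
#' @param monthly List of exactly 12 co-registered continuous `grid_raster`s.
#' @param stat `"mean"` or `"sum"`.
#' @return Continuous `grid_raster`.
#' @export
climate_annual <- function(monthly, stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  if (length(monthly) != 12L) {
    stop("climate_annual expects exactly 12 monthly rasters", call. = FALSE)
  }
  g <- monthly[[1]]$grid
  for (m in monthly[-1]) check_same_grid(g, m$grid, "monthly rasters")
  acc <- matrix(0, g$n_rows, g$n_cols)
  for (m in monthly) acc <- acc + m$values   # NA propagates
  if (stat == "mean") acc <- acc / 12
  grid_raster(g, acc, "continuous")
}

#' Line frame for priority-tagged ways
#'
#' @param geometry List of two-column lon/lat matrices (polylines).
#' @param priority Integer road class 1-17 (footpath to motorway); bridge/
#'   tunnel links carry the reserved value 30.
#' @param name,ref,junction Optional way tags (default `NA`).
#' @param link Logical bridge-or-tunnel flag (default `FALSE`).
#' @return Tibble with class `line_frame`.
#' @export
line_frame <- function(geometry, priority, name = NA_character_,
                       ref = NA_character_, junction = NA_character_,
                       link = FALSE) {
  n <- length(geometry)
  out <- tibble::tibble(
    geometry = lapply(geometry, function(m) unname(as.matrix(m))),
    priority = as.numeric(rep_len(priority, n)),
    name = rep_len(as.character(name), n),
    ref = rep_len(as.character(ref), n),
    junction = rep_len(as.character(junction), n),
    link = rep_len(as.logical(link), n)
  )
  if (any(!(out$priority %in% c(1:17, 30)))) {
    stop("way priorities must be 1-17, or 30 for links", call. = FALSE)
  }
  class(out) <- c("line_frame", class(out))
  out
}

#' Rasterise the maximum road priority per cell
#'
#' Every cell whose closed square is touched by at least one retained way
#' receives the maximum priority among the ways touching it; all other cells
#' get 0 (background land). Ways outside the retained class range are
#' ignored. Classes 8-30 (tertiary to motorway, plus links) are the major
#' routes retained by default.
#'
#' @param lines A [line_frame()].
#' @param grid Target [mastergrid()].
#' @param retain Numeric `c(min, max)` priority range kept (default
#'   `c(8, 30)`).
#' @return Continuous `grid_raster` (0 = no retained road).
#' @export
priority_rasterize <- function(lines, grid, retain = c(8, 30)) {
  vals <- matrix(0, grid$n_rows, grid$n_cols)
  if (nrow(lines)) {
    keep <- lines$priority >= retain[1] & lines$priority <= retain[2]
    for (i in which(keep)) {
      hit <- cells_hit_by_line(lines$geometry[[i]], grid)
      if (nrow(hit)) {
        vals[hit] <- pmax(vals[hit], lines$priority[i])
      }
    }
  }
  grid_raster(grid, vals, "continuous")
}

#' Restore offshore bridge/tunnel links after coastal standardisation
#'
#' Standardising roads to the coastline wipes bridges and tunnels that cross
#' water; this writes link cells that lie off land back into the highway
#' raster (value 30) so coastal roads remain contiguous. On-land link cells
#' are discarded - only offshore features are restored.
#'
#' @param highways `grid_raster` of road priorities (0 background).
#' @param links Binary or priority `grid_raster` marking link cells.
#' @param land Co-registered binary land mask.
#' @return Adjusted highway `grid_raster`.
#' @export
restore_offshore_links <- function(highways, links, land) {
  check_same_grid(highways$grid, links$grid)
  check_same_grid(highways$grid, land$grid)
  offshore <- !is.na(links$values) & links$values > 0 &
    (is.na(land$values) | land$values == 0)
  vals <- highways$values
  vals[offshore] <- 30
  grid_raster(highways$grid, vals, highways$kind)
}

#' Detect significant highway intersections
#'
#' A highway is taken to run with uniform name, reference, junction and
#' priority tags; where two ways in the retained classes touch or cross and
#' differ in at least one of those tags, an intersection point is emitted at
#' the crossing. Crossings where either way is a bridge or tunnel are
#' suppressed (no at-grade intersection exists there), and duplicate points
#' are removed.
#'
#' @param lines A [line_frame()].
#' @param classes Numeric `c(min, max)` priority range considered (default
#'   `c(8, 17)`).
#' @return Tibble of intersection points (`lon`, `lat`).
#' @export
detect_intersections <- function(lines, classes = c(8, 17)) {
  keep <- which(lines$priority >= classes[1] & lines$priority <= classes[2])
  pts <- matrix(numeric(0), 0, 2)
  tag <- function(i) c(lines$name[i], lines$ref[i], lines$junction[i],
                       lines$priority[i])
  if (length(keep) >= 2) {
    for (a in keep) for (b in keep[keep > a]) {
      if (isTRUE(lines$link[a]) || isTRUE(lines$link[b])) next
      if (identical(tag(a), tag(b))) next
      ga <- lines$geometry[[a]]; gb <- lines$geometry[[b]]
      for (i in seq_len(nrow(ga) - 1)) for (j in seq_len(nrow(gb) - 1)) {
        p <- segment_intersection(ga[i, ], ga[i + 1, ], gb[j, ], gb[j + 1, ])
        if (!is.null(p)) pts <- rbind(pts, p)
      }
    }
  }
  out <- tibble::tibble(lon = round(pts[, 1], 9), lat = round(pts[, 2], 9))
  dplyr::distinct(out)
}

#' Assemble a contiguous natural-water layer
#'
#' Mosaics waterbodies onto riverbanks, and riverbanks onto waterways:
#' the union of the three binary layers, with the listed priority deciding
#' which source a cell is attributed to (not its value, which is 1 for all).
#'
#' @param waterbodies,riverbanks,waterways Co-registered binary
#'   `grid_raster`s (any may be NULL).
#' @return Binary `grid_raster` union.
#' @export
waterway_union <- function(waterbodies = NULL, riverbanks = NULL,
                           waterways = NULL) {
  layers <- Filter(Negate(is.null), list(waterbodies, riverbanks, waterways))
  if (!length(layers)) stop("no water layers supplied", call. = FALSE)
  g <- layers[[1]]$grid
  out <- matrix(NA_real_, g$n_rows, g$n_cols)
  for (l in layers) {
    check_same_grid(g, l$grid, "water layers")
    v <- l$values
    out[!is.na(v) & v == 1] <- 1
    out[!is.na(v) & v == 0 & is.na(out)] <- 0
  }
  grid_raster(g, out, "binary")
}
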
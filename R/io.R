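#' Read and write rasters as ESRI ASCII grids
#'
#' Rasters are exchanged as plain-text ESRI ASCII grids (`.asc`), which carry
#' the georeferencing (corner, cell size, no-data sentinel) inline and are
#' understood by every mainstream GIS. Values are written at full double
#' precision.
#'
#' @param x A `grid_raster`.
#' @param path File path.
#' @return `write_ascii_grid()` returns `path` invisibly; `read_ascii_grid()`
#'   returns a `grid_raster`.
#' @export
write_ascii_grid <- function(x, path) {
  g <- x$grid
  ext <- grid_extent(g)
  vals <- x$values
  vals[is.na(vals)] <- g$nodata
  header <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.17g", ext[["west"]]),
    sprintf("yllcorner %.17g", ext[["south"]]),
    sprintf("cellsize %.17g", g$cell_size),
    sprintf("NODATA_value %.17g", g$nodata)
  )
  rows <- apply(vals, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param kind Raster kind to assign on read (default `"continuous"`).
#' @export
read_ascii_grid <- function(path, kind = "continuous") {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  n_cols <- as.integer(val("ncols")); n_rows <- as.integer(val("nrows"))
  cs <- val("cellsize"); nodata <- val("NODATA_value")
  g <- mastergrid(cell_size = cs,
                  origin_lon = val("xllcorner"),
                  origin_lat = val("yllcorner") + n_rows * cs,
                  n_rows = n_rows, n_cols = n_cols, nodata = nodata)
  vals <- matrix(as.numeric(unlist(strsplit(trimws(lines[-(1:6)]), "\\s+"))),
                 nrow = n_rows, ncol = n_cols, byrow = TRUE)
  grid_raster(g, vals, kind)
}

#' Serialise a mastergrid definition to JSON
#'
#' @param grid A `mastergrid`.
#' @param path JSON file path.
#' @return `write_grid_config()` returns `path` invisibly;
#'   `read_grid_config()` returns a `mastergrid`.
#' @export
write_grid_config <- function(grid, path) {
  jsonlite::write_json(unclass(grid), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grid_config
#' @export
read_grid_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  mastergrid(cfg$cell_size, cfg$origin_lon, cfg$origin_lat,
             cfg$n_rows, cfg$n_cols, cfg$nodata)
}

geojson_feature <- function(geometry_type, coords, properties) {
  list(type = "Feature", properties = properties,
       geometry = list(type = geometry_type, coordinates = coords))
}

write_feature_collection <- function(features, path) {
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_feature_collection <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)$features
}

coords_to_matrix <- function(coords) {
  do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
}

#' GeoJSON I/O for admin polygons
#'
#' @param polygons A [polygon_frame()].
#' @param path File path.
#' @return Writers return `path` invisibly; readers return the frame.
#' @export
write_polygons_geojson <- function(polygons, path) {
  feats <- purrr::map2(polygons$id, polygons$geometry, function(id, ring) {
    ring <- rbind(ring, ring[1, ])   # GeoJSON rings are closed
    geojson_feature("Polygon", list(apply(ring, 1, as.list, simplify = FALSE)),
                    list(id = id))
  })
  write_feature_collection(feats, path)
}

#' @rdname write_polygons_geojson
#' @export
read_polygons_geojson <- function(path) {
  feats <- read_feature_collection(path)
  polygon_frame(
    id = vapply(feats, function(f) as.numeric(f$properties$id), numeric(1)),
    geometry = lapply(feats, function(f) {
      coords_to_matrix(f$geometry$coordinates[[1]])
    })
  )
}

#' GeoJSON I/O for priority-tagged ways
#'
#' @param lines A [line_frame()].
#' @param path File path.
#' @return Writers return `path` invisibly; readers return the frame.
#' @export
write_lines_geojson <- function(lines, path) {
  feats <- purrr::map(seq_len(nrow(lines)), function(i) {
    geojson_feature(
      "LineString",
      apply(lines$geometry[[i]], 1, as.list, simplify = FALSE),
      list(priority = lines$priority[i], name = lines$name[i],
           ref = lines$ref[i], junction = lines$junction[i],
           link = lines$link[i])
    )
  })
  write_feature_collection(feats, path)
}

#' @rdname write_lines_geojson
#' @export
read_lines_geojson <- function(path) {
  feats <- read_feature_collection(path)
  p <- function(f, key, default = NA) {
    v <- f$properties[[key]]
    if (is.null(v)) default else v
  }
  line_frame(
    geometry = lapply(feats, function(f) coords_to_matrix(f$geometry$coordinates)),
    priority = vapply(feats, function(f) as.numeric(p(f, "priority")), numeric(1)),
    name = vapply(feats, function(f) as.character(p(f, "name")), character(1)),
    ref = vapply(feats, function(f) as.character(p(f, "ref")), character(1)),
    junction = vapply(feats, function(f) as.character(p(f, "junction")),
                      character(1)),
    link = vapply(feats, function(f) isTRUE(p(f, "link", FALSE)), logical(1))
  )
}

#' GeoJSON I/O for event points
#'
#' @param events An [event_set()].
#' @param path File path.
#' @return Writers return `path` invisibly; readers return the event set.
#' @export
write_events_geojson <- function(events, path) {
  feats <- purrr::map(seq_len(nrow(events)), function(i) {
    geojson_feature("Point", list(events$lon[i], events$lat[i]),
                    list(year = events$year[i]))
  })
  write_feature_collection(feats, path)
}

#' @rdname write_events_geojson
#' @export
read_events_geojson <- function(path) {
  feats <- read_feature_collection(path)
  event_set(
    lon = vapply(feats, function(f) as.numeric(f$geometry$coordinates[[1]]),
                 numeric(1)),
    lat = vapply(feats, function(f) as.numeric(f$geometry$coordinates[[2]]),
                 numeric(1)),
    year = vapply(feats, function(f) as.numeric(f$properties$year), numeric(1))
  )
}

#' Census table CSV I/O
#'
#' The interchange schema is `unit_id, parent_id, P1, year1, P2, year2` (one
#' row per unit, two census dates); annual series are written long as
#' `unit_id, year, count`.
#'
#' @param records Census tibble.
#' @param path File path.
#' @return Writers return `path` invisibly; the reader returns a tibble.
#' @export
write_census_csv <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_census_csv
#' @export
read_census_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
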
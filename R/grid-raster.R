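#' Raster aligned to a mastergrid
#'
#' A `grid_raster` pairs a [mastergrid()] with an `n_rows x n_cols` value
#' matrix and a declared kind. No-data cells are stored as `NA` internally;
#' the grid's `nodata` sentinel is used only on disk.
#'
#' @param grid A `mastergrid`.
#' @param values Numeric matrix with `grid$n_rows` rows and `grid$n_cols`
#'   columns, or a single value to fill the raster. Cells equal to
#'   `grid$nodata` are converted to `NA`.
#' @param kind One of `"continuous"`, `"categorical"`, `"binary"`. Binary
#'   rasters may contain only 0, 1 and `NA`.
#' @return A `grid_raster`.
#' @export
grid_raster <- function(grid, values,
                        kind = c("continuous", "categorical", "binary")) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "mastergrid"))
  if (length(values) == 1L) {
    values <- matrix(as.numeric(values), grid$n_rows, grid$n_cols)
  }
  stopifnot(is.matrix(values))
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols) {
    stop("value matrix dimensions do not match the mastergrid", call. = FALSE)
  }
  storage.mode(values) <- "double"
  values[!is.na(values) & values == grid$nodata] <- NA_real_
  if (kind == "binary") {
    bad <- !is.na(values) & !(values %in% c(0, 1))
    if (any(bad)) {
      stop("binary raster contains values other than {0, 1, nodata}",
           call. = FALSE)
    }
  }
  structure(list(grid = grid, values = values, kind = kind),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<grid_raster:%s> %d x %d, %d nodata cells\n",
              x$kind, nrow(v), ncol(v), sum(is.na(v))))
  if (x$kind == "continuous") {
    cat(sprintf("  range: [%.6g, %.6g]\n",
                suppressWarnings(min(v, na.rm = TRUE)),
                suppressWarnings(max(v, na.rm = TRUE))))
  } else {
    u <- sort(unique(v[!is.na(v)]))
    cat("  classes:", paste(utils::head(u, 12), collapse = " "),
        if (length(u) > 12) "..." else "", "\n")
  }
  invisible(x)
}

# shorthand for a raster that reuses the grid of `like`
raster_like <- function(like, values, kind = like$kind) {
  grid_raster(like$grid, values, kind)
}

#' Convert a grid_raster to a long tibble
#'
#' One row per cell with row/col indices, centre coordinates and value;
#' convenient for dplyr/ggplot2 work.
#'
#' @param x A `grid_raster`.
#' @param ... Unused.
#' @param drop_na Drop no-data cells (default TRUE).
#' @return A tibble with columns `row`, `col`, `lon`, `lat`, `value`.
#' @method as_tibble grid_raster
#' @export
as_tibble.grid_raster <- function(x, ..., drop_na = TRUE) {
  g <- x$grid
  out <- tibble::tibble(
    row = rep(seq_len(g$n_rows), times = g$n_cols),
    col = rep(seq_len(g$n_cols), each = g$n_rows),
    lon = rep(cell_lon(g), each = g$n_rows),
    lat = rep(cell_lat(g), times = g$n_cols),
    value = as.vector(x$values)
  )
  if (drop_na) out <- dplyr::filter(out, !is.na(.data$value))
  out
}

#' Raster heat-map
#'
#' @param object A `grid_raster`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot grid_raster
#' @export
autoplot.grid_raster <- function(object, ...) {
  df <- as_tibble.grid_raster(object, drop_na = FALSE)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat)) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "longitude", y = "latitude")
  if (object$kind == "continuous") {
    p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_viridis_c(na.value = "grey90")
  } else {
    p + ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$value))) +
      ggplot2::scale_fill_viridis_d(na.value = "grey90", name = "class")
  }
}
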
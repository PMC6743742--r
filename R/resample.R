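#' Align a raster to a target mastergrid
#'
#' Standardises a source raster onto the target grid definition. `nearest`
#' and `bilinear` sample at target cell centres; `block_average` takes the
#' mean of source cells whose centres fall inside each target cell, ignoring
#' no-data (the usual choice when aggregating a finer grid). Target cells
#' with no source coverage are no-data. Categorical and binary rasters may
#' only be resampled with `nearest`.
#'
#' @param src Source `grid_raster`.
#' @param target Target [mastergrid()].
#' @param method `"nearest"`, `"bilinear"` or `"block_average"`.
#' @return A `grid_raster` on `target`.
#' @export
align_to_mastergrid <- function(src, target,
                                method = c("nearest", "bilinear",
                                           "block_average")) {
  method <- match.arg(method)
  stopifnot(inherits(src, "grid_raster"), inherits(target, "mastergrid"))
  if (src$kind != "continuous" && method != "nearest") {
    stop(sprintf("%s resampling is not defined for %s rasters; use nearest",
                 method, src$kind), call. = FALSE)
  }
  sg <- src$grid
  sext <- grid_extent(sg)
  out <- matrix(NA_real_, target$n_rows, target$n_cols)

  if (method %in% c("nearest", "bilinear")) {
    tx <- rep(cell_lon(target), each = target$n_rows)
    ty <- rep(cell_lat(target), times = target$n_cols)
    covered <- tx >= sext["west"] & tx < sext["east"] &
      ty > sext["south"] & ty <= sext["north"]
    if (method == "nearest") {
      sc <- floor((tx - sext["west"]) / sg$cell_size) + 1
      sr <- floor((sext["north"] - ty) / sg$cell_size) + 1
      ok <- covered
      out[ok] <- src$values[cbind(sr[ok], sc[ok])]
    } else {
      # fractional position in source cell-centre coordinates
      fx <- (tx - sext["west"]) / sg$cell_size - 0.5
      fy <- (sext["north"] - ty) / sg$cell_size - 0.5
      c0 <- pmin(pmax(floor(fx) + 1, 1), sg$n_cols - 1)
      r0 <- pmin(pmax(floor(fy) + 1, 1), sg$n_rows - 1)
      wx <- pmin(pmax(fx - (c0 - 1), 0), 1)
      wy <- pmin(pmax(fy - (r0 - 1), 0), 1)
      v00 <- src$values[cbind(r0, c0)]
      v01 <- src$values[cbind(r0, c0 + 1)]
      v10 <- src$values[cbind(r0 + 1, c0)]
      v11 <- src$values[cbind(r0 + 1, c0 + 1)]
      val <- (1 - wy) * ((1 - wx) * v00 + wx * v01) +
        wy * ((1 - wx) * v10 + wx * v11)
      out[covered] <- val[covered]
    }
  } else {
    # assign every source cell centre to a target cell, then average
    sx <- rep(cell_lon(sg), each = sg$n_rows)
    sy <- rep(cell_lat(sg), times = sg$n_cols)
    text <- grid_extent(target)
    inside <- sx >= text["west"] & sx < text["east"] &
      sy > text["south"] & sy <= text["north"]
    v <- as.vector(src$values)
    keep <- inside & !is.na(v)
    if (any(keep)) {
      tc <- floor((sx[keep] - text["west"]) / target$cell_size) + 1
      tr <- floor((text["north"] - sy[keep]) / target$cell_size) + 1
      idx <- (tc - 1) * target$n_rows + tr
      sums <- rowsum(v[keep], idx)
      cnts <- rowsum(rep(1, length(idx)), idx)
      out[as.integer(rownames(sums))] <- sums / cnts
    }
  }
  grid_raster(target, out, src$kind)
}

#' Fill coastal no-data cells from nearest data values ("nibble")
#'
#' Land cells (mask = 1) that are no-data in `src` receive the value of the
#' nearest data cell, by Euclidean distance in cell units; ties are broken by
#' smallest row index, then smallest column. Ocean cells are forced to
#' no-data and existing data cells are never altered. Filling is done in
#' floating point directly (no integer scaling is needed).
#'
#' @param src Continuous `grid_raster` with coastal gaps.
#' @param land_mask Co-registered binary `grid_raster` (1 = land).
#' @return A `grid_raster` with every land cell carrying data.
#' @export
coastal_fill_nibble <- function(src, land_mask) {
  check_same_grid(src$grid, land_mask$grid)
  if (land_mask$kind != "binary") {
    stop("land_mask must be binary", call. = FALSE)
  }
  land <- !is.na(land_mask$values) & land_mask$values == 1
  vals <- src$values
  vals[!land] <- NA_real_
  gaps <- which(land & is.na(vals))
  if (length(gaps) == 0L) return(grid_raster(src$grid, vals, src$kind))
  donors <- which(!is.na(vals))
  if (length(donors) == 0L) {
    stop("cannot nibble: no data cells available to fill land gaps",
         call. = FALSE)
  }
  nr <- src$grid$n_rows
  dr <- ((donors - 1L) %% nr) + 1L
  dc <- ((donors - 1L) %/% nr) + 1L
  gr <- ((gaps - 1L) %% nr) + 1L
  gc <- ((gaps - 1L) %/% nr) + 1L
  # donor order encodes the tie-break: smallest row, then smallest column
  ord <- order(dr, dc)
  dr <- dr[ord]; dc <- dc[ord]; dv <- vals[donors][ord]
  fill <- vapply(seq_along(gaps), function(i) {
    d2 <- (dr - gr[i])^2 + (dc - gc[i])^2
    dv[which.min(d2)]
  }, numeric(1))
  vals[gaps] <- fill
  grid_raster(src$grid, vals, src$kind)
}
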
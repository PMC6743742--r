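#' Annual DMSP night-lights composite
#'
#' Years observed by two satellites are averaged cell-wise; single-satellite
#' years pass through unchanged. Cells with no coverage (polar gaps) are
#' replaced with zero radiance. Inputs are assumed pre-calibrated
#' (inter-calibrated digital numbers, x100 scaling).
#'
#' @param sat_a Continuous `grid_raster` of annual radiance.
#' @param sat_b Optional second satellite for the same year (or NULL).
#' @return Continuous `grid_raster`.
#' @export
dmsp_annual_composite <- function(sat_a, sat_b = NULL) {
  v <- sat_a$values
  if (!is.null(sat_b)) {
    check_same_grid(sat_a$grid, sat_b$grid)
    w <- sat_b$values
    both <- !is.na(v) & !is.na(w)
    v[both] <- (v[both] + w[both]) / 2
    v[is.na(v) & !is.na(w)] <- w[is.na(v) & !is.na(w)]
  }
  v[is.na(v)] <- 0   # polar no-coverage becomes zero radiance
  grid_raster(sat_a$grid, v, "continuous")
}

#' Monthly VIIRS stack for one year
#'
#' @param year Composite year.
#' @param radiance List of monthly average-radiance `grid_raster`s (12, or 9
#'   for a partial first year).
#' @param observations Matching list of cloud-free observation-count rasters
#'   (integers >= 0).
#' @return A `viirs_stack`.
#' @export
viirs_stack <- function(year, radiance, observations) {
  if (length(radiance) != length(observations)) {
    stop("radiance and observation stacks differ in length", call. = FALSE)
  }
  if (!length(radiance) %in% c(9L, 12L)) {
    stop("expected 12 monthly rasters (or 9 for a partial year)", call. = FALSE)
  }
  g <- radiance[[1]]$grid
  for (x in c(radiance, observations)) check_same_grid(g, x$grid, "stack")
  structure(list(year = year, radiance = radiance,
                 observations = observations),
            class = "viirs_stack")
}

#' Annual VIIRS night-lights composite
#'
#' Per cell, monthly radiances are summed over the months with at least one
#' cloud-free observation and divided by the number of such months (monthly
#' inputs are already month-averaged, so attenuation is by months observed,
#' not by total observations). Cells never observed are no-data, then filled
#' from surrounding values by an iterative 3x3 mean over valid neighbours
#' (in-place sweep, top-left to bottom-right) until no gap remains.
#'
#' @param stack A [viirs_stack()].
#' @param fill Fill unobserved cells from neighbours (default TRUE).
#' @return Continuous `grid_raster` of annual average radiance.
#' @export
viirs_annual_composite <- function(stack, fill = TRUE) {
  g <- stack$radiance[[1]]$grid
  nr <- g$n_rows; nc <- g$n_cols
  ssum <- matrix(0, nr, nc)
  m_obs <- matrix(0, nr, nc)
  for (k in seq_along(stack$radiance)) {
    obs <- stack$observations[[k]]$values
    rad <- stack$radiance[[k]]$values
    seen <- !is.na(obs) & obs > 0
    add <- ifelse(seen & !is.na(rad), rad, 0)
    ssum <- ssum + add
    m_obs <- m_obs + as.numeric(seen)
  }
  if (all(m_obs == 0)) {
    stop("no cell has any cloud-free observation", call. = FALSE)
  }
  vals <- matrix(NA_real_, nr, nc)
  vals[m_obs > 0] <- ssum[m_obs > 0] / m_obs[m_obs > 0]
  if (fill) vals <- focal_mean_fill(vals)
  grid_raster(g, vals, "continuous")
}

# Iterative gap fill: sweep rows then columns; a gap with >= 1 valid
# 8-neighbour takes their mean (updates visible within the sweep), repeated
# until no gap remains or nothing changes.
focal_mean_fill <- function(vals) {
  nr <- nrow(vals); nc <- ncol(vals)
  repeat {
    gaps <- which(is.na(vals))
    if (!length(gaps)) break
    changed <- FALSE
    for (idx in gaps) {
      r <- ((idx - 1L) %% nr) + 1L
      cc <- ((idx - 1L) %/% nr) + 1L
      rs <- max(1, r - 1):min(nr, r + 1)
      cs <- max(1, cc - 1):min(nc, cc + 1)
      nb <- vals[rs, cs]
      nb <- nb[!is.na(nb)]
      if (length(nb)) {
        vals[r, cc] <- mean(nb)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  vals
}

#' Protected-area feature set
#'
#' @param geometry List of lon/lat matrices (polygon rings) or length-2
#'   numeric vectors (points).
#' @param designation_year Year each area was designated (<= 2017).
#' @param iucn_group `"strict1"` (IUCN Ia/Ib) or `"other"`.
#' @param domain `"terrestrial"` or `"marine"` (marine/coastal).
#' @param buffer_m Radius in metres used to turn point features into circles
#'   (default 70).
#' @return Tibble with class `protected_areas`.
#' @export
protected_areas <- function(geometry, designation_year, iucn_group, domain,
                            buffer_m = 70) {
  n <- length(geometry)
  out <- tibble::tibble(
    geometry = geometry,
    designation_year = as.numeric(rep_len(designation_year, n)),
    iucn_group = rep_len(as.character(iucn_group), n),
    domain = rep_len(as.character(domain), n),
    buffer_m = as.numeric(rep_len(buffer_m, n))
  )
  if (any(out$designation_year > 2017)) {
    stop("designation years beyond 2017 are not supported", call. = FALSE)
  }
  if (!all(out$iucn_group %in% c("strict1", "other"))) {
    stop("iucn_group must be 'strict1' or 'other'", call. = FALSE)
  }
  if (!all(out$domain %in% c("terrestrial", "marine"))) {
    stop("domain must be 'terrestrial' or 'marine'", call. = FALSE)
  }
  if (any(out$buffer_m <= 0)) stop("buffer radius must be > 0", call. = FALSE)
  class(out) <- c("protected_areas", class(out))
  out
}

# cells covered by one protected-area feature (centre-point test; points are
# buffered to circles of buffer_m metres)
pa_feature_cells <- function(geom, buffer_m, grid, earth) {
  if (is.matrix(geom)) {
    lon <- cell_lon(grid); lat <- cell_lat(grid)
    px <- rep(lon, each = grid$n_rows)
    py <- rep(lat, times = grid$n_cols)
    which(point_in_ring(px, py, geom))
  } else {
    lon <- cell_lon(grid); lat <- cell_lat(grid)
    pts <- cbind(rep(lon, each = grid$n_rows), rep(lat, times = grid$n_cols))
    d <- geosphere::distHaversine(pts, geom, r = earth$R)
    which(d <= buffer_m)
  }
}

#' Cumulative annual protected-area series
#'
#' For each year, IUCN group and domain, a binary raster marks cells covered
#' by any area designated in that year or earlier (the first year includes
#' all prior designations, so the series is cumulative by construction).
#' With 18 years x 2 groups x 2 domains this yields 72 pre-mosaic rasters;
#' mosaicking terrestrial onto marine/coastal per group then gives 36 final
#' rasters, two per year.
#'
#' @param pa A [protected_areas()] set.
#' @param grid Target [mastergrid()].
#' @param years Years of the series (default 2000:2017).
#' @param earth An [earth_model()] (for point buffering).
#' @return List with `premosaic` (named list of binary rasters,
#'   `<year>_<group>_<domain>`) and `final` (named list, `<year>_<group>`).
#' @export
wdpa_annual_series <- function(pa, grid, years = 2000:2017,
                               earth = earth_model()) {
  stopifnot(inherits(grid, "mastergrid"))
  groups <- c("strict1", "other")
  domains <- c("terrestrial", "marine")
  # cell sets per feature, computed once
  cells <- lapply(seq_len(nrow(pa)), function(i) {
    pa_feature_cells(pa$geometry[[i]], pa$buffer_m[i], grid, earth)
  })
  premosaic <- list()
  final <- list()
  for (y in years) {
    for (gname in groups) {
      per_domain <- list()
      for (d in domains) {
        sel <- which(pa$designation_year <= y & pa$iucn_group == gname &
                       pa$domain == d)
        vals <- matrix(0, grid$n_rows, grid$n_cols)
        for (i in sel) vals[cells[[i]]] <- 1
        r <- grid_raster(grid, vals, "binary")
        premosaic[[sprintf("%d_%s_%s", y, gname, d)]] <- r
        per_domain[[d]] <- r
      }
      # terrestrial mosaicked onto the marine/coastal counterpart
      u <- pmax(per_domain$marine$values, per_domain$terrestrial$values)
      final[[sprintf("%d_%s", y, gname)]] <- grid_raster(grid, u, "binary")
    }
  }
  list(premosaic = premosaic, final = final)
}

#' Fused built-settlement series for 2000, 2012 and 2014
#'
#' The 2000 layer is the GHSL 2000 extent plus those ESA CCI 2000 built
#' pixels that the (more reliable, radar-based) GUF 2012 layer also classes
#' as settlement - the back-filter limits where optical commission errors
#' can fill GHSL gaps. 2012 mosaics GUF 2012 onto the 2000 layer; 2014
#' mosaics GHSL 2014 onto GUF 2012.
#'
#' @param ghsl2000,esa2000_built,guf2012,ghsl2014 Co-registered binary
#'   `grid_raster`s.
#' @return Named list of binary rasters `year2000`, `year2012`, `year2014`.
#' @export
built_settlement_series <- function(ghsl2000, esa2000_built, guf2012,
                                    ghsl2014) {
  g <- ghsl2000$grid
  for (x in list(esa2000_built, guf2012, ghsl2014)) {
    check_same_grid(g, x$grid)
  }
  b <- function(r) !is.na(r$values) & r$values == 1
  as_bin <- function(m) grid_raster(g, matrix(as.numeric(m), g$n_rows,
                                              g$n_cols), "binary")
  y2000 <- b(ghsl2000) | (b(esa2000_built) & b(guf2012))
  y2012 <- y2000 | b(guf2012)
  y2014 <- b(guf2012) | b(ghsl2014)
  list(year2000 = as_bin(y2000), year2012 = as_bin(y2012),
       year2014 = as_bin(y2014))
}
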
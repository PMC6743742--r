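#' Population at risk under a prevalence threshold
#'
#' Per zone, sums the gridded population over cells where prevalence exceeds
#' the threshold (strict inequality; the conventional cut is >10%), and
#' reports the zonal total and the percentage at risk.
#'
#' @param pop Population `grid_raster` (persons per cell).
#' @param prevalence Co-registered `grid_raster` with values in \[0, 1\].
#' @param zones Admin-ID `grid_raster` defining reporting zones.
#' @param threshold Prevalence fraction above which a cell is at risk
#'   (default 0.10).
#' @return Risk tibble: `zone_id`, `population_at_risk`, `total_population`,
#'   `percent_at_risk`.
#' @export
population_at_risk <- function(pop, prevalence, zones, threshold = 0.10) {
  check_same_grid(pop$grid, prevalence$grid)
  check_same_grid(pop$grid, zones$grid)
  pv <- prevalence$values
  if (any(!is.na(pv) & (pv < 0 | pv > 1))) {
    stop("prevalence values must lie in [0, 1]", call. = FALSE)
  }
  ids <- admin_unit_ids(zones)
  z <- as.vector(zones$values)
  p <- as.vector(pop$values)
  at <- !is.na(as.vector(pv)) & as.vector(pv) > threshold
  purrr::map_dfr(ids, function(u) {
    in_u <- !is.na(z) & z == u
    total <- sum(p[in_u], na.rm = TRUE)
    risk <- sum(p[in_u & at], na.rm = TRUE)
    tibble::tibble(zone_id = u,
                   population_at_risk = risk,
                   total_population = total,
                   percent_at_risk = if (total > 0) 100 * risk / total
                                     else NA_real_)
  })
}

#' Change metrics between two risk tables
#'
#' Reports, per zone, the log10 at-risk counts at both dates, their
#' difference (equivalently the log10 of the ratio), and the
#' percentage-point change in the share at risk. Zones with a zero at-risk
#' count at either date get `NA` log fields rather than a fabricated value.
#'
#' @param t1,t2 Risk tibbles from [population_at_risk()] over matching zones.
#' @return Tibble `zone_id`, `log10_at_risk_t1`, `log10_at_risk_t2`,
#'   `log10_change`, `percent_point_change`.
#' @export
risk_change_metrics <- function(t1, t2) {
  if (!setequal(t1$zone_id, t2$zone_id)) {
    stop("risk tables cover different zone sets", call. = FALSE)
  }
  dplyr::inner_join(t1, t2, by = "zone_id", suffix = c("_t1", "_t2")) |>
    dplyr::transmute(
      zone_id = .data$zone_id,
      log10_at_risk_t1 = ifelse(.data$population_at_risk_t1 > 0,
                                log10(.data$population_at_risk_t1), NA_real_),
      log10_at_risk_t2 = ifelse(.data$population_at_risk_t2 > 0,
                                log10(.data$population_at_risk_t2), NA_real_),
      log10_change = .data$log10_at_risk_t2 - .data$log10_at_risk_t1,
      percent_point_change = .data$percent_at_risk_t2 - .data$percent_at_risk_t1
    )
}

#' Conflict-event set
#'
#' @param lon,lat Event coordinates (decimal degrees).
#' @param year Event year.
#' @return Tibble `lon`, `lat`, `year` with class `event_set`.
#' @export
event_set <- function(lon = numeric(), lat = numeric(), year = numeric()) {
  out <- tibble::tibble(lon = as.numeric(lon), lat = as.numeric(lat),
                        year = as.numeric(rep_len(year, length(lon))))
  class(out) <- c("event_set", class(out))
  out
}

#' Flag fixed square zones containing clustered conflict events
#'
#' The grid extent is partitioned into fixed, grid-aligned square blocks of
#' `zone_km` side (9 x 9 km by default; the east-west cell span of each
#' block row is converted from km at that row's central latitude). A block
#' is flagged when it contains at least `min_events` events, and all cells
#' of flagged blocks are marked 1. A partition - not a moving window - keeps
#' zones deterministic and disjoint.
#'
#' @param events An [event_set()] (locations must fall inside the grid).
#' @param grid Target [mastergrid()].
#' @param zone_km Zone side in kilometres (default 9).
#' @param min_events Minimum events per flagged zone (default 2).
#' @param earth An [earth_model()].
#' @return Binary `grid_raster` of flagged zones.
#' @export
conflict_zones <- function(events, grid, zone_km = 9, min_events = 2,
                           earth = earth_model()) {
  if (zone_km <= 0) stop("zone size must be positive", call. = FALSE)
  ext <- grid_extent(grid)
  s <- grid$cell_size
  zone_m <- zone_km * 1000
  # north-south block height in cells (metric row spacing is constant)
  cell_m_y <- earth$R * s * pi / 180
  ny <- max(1L, as.integer(round(zone_m / cell_m_y)))
  n_brow <- ceiling(grid$n_rows / ny)
  vals <- matrix(0, grid$n_rows, grid$n_cols)
  if (nrow(events)) {
    inside <- events$lon >= ext["west"] & events$lon < ext["east"] &
      events$lat > ext["south"] & events$lat <= ext["north"]
    if (!all(inside)) {
      stop("event location(s) outside the grid extent", call. = FALSE)
    }
  }
  er <- if (nrow(events)) {
    pmin(floor((ext["north"] - events$lat) / s) + 1, grid$n_rows)
  } else integer(0)
  ec <- if (nrow(events)) {
    pmin(floor((events$lon - ext["west"]) / s) + 1, grid$n_cols)
  } else integer(0)
  for (br in seq_len(n_brow)) {
    r0 <- (br - 1L) * ny + 1L
    r1 <- min(br * ny, grid$n_rows)
    lat_mid <- (cell_lat(grid)[r0] + cell_lat(grid)[r1]) / 2
    cell_m_x <- earth$R * cos(lat_mid * pi / 180) * s * pi / 180
    nx <- max(1L, as.integer(round(zone_m / cell_m_x)))
    in_row <- er >= r0 & er <= r1
    if (!any(in_row)) next
    bcol <- (ec[in_row] - 1L) %/% nx
    tab <- table(bcol)
    flagged <- as.integer(names(tab)[tab >= min_events])
    for (bc in flagged) {
      c0 <- bc * nx + 1L
      c1 <- min((bc + 1L) * nx, grid$n_cols)
      vals[r0:r1, c0:c1] <- 1
    }
  }
  grid_raster(grid, vals, "binary")
}

#' Regional population living in proximity to conflict
#'
#' Per region, sums the gridded population over flagged conflict-zone cells
#' and reports it as a share of the regional total.
#'
#' @param pop Population `grid_raster`.
#' @param flagged Binary `grid_raster` from [conflict_zones()].
#' @param regions Admin-ID `grid_raster` of reporting regions.
#' @return Risk tibble: `zone_id`, `population_at_risk` (proximal
#'   population), `total_population`, `percent_at_risk`.
#' @export
population_near_conflict <- function(pop, flagged, regions) {
  check_same_grid(pop$grid, flagged$grid)
  # proximity is just an at-risk query with the flag as a 0/1 "prevalence"
  population_at_risk(pop, flagged, regions, threshold = 0.5)
}

#' Bar chart of a risk table
#'
#' @param object Risk tibble from [population_at_risk()] or
#'   [population_near_conflict()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_risk_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(factor(.data$zone_id), .data$percent_at_risk)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = "zone", y = "% of population at risk")
}
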
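#' Configuration for a synthetic toy world
#'
#' Defines the generative parameters of a seeded toy study area: extent and
#' resolution, the administrative hierarchy, the log-linear population model
#' (`log density = beta0 + sum(beta_i * cov_i) + noise`), per-unit growth
#' rates, the prevalence field and the conflict-event process. Defaults give
#' a 1 degree x 1 degree extent at 0.01 degree cells (100 x 100), 4
#' countries x 25 units and noise sigma 0.2.
#'
#' @param seed Integer seed (mandatory); all generation is deterministic
#'   given the config.
#' @param extent `c(west, south, east, north)` in degrees.
#' @param cell_size Cell edge in degrees.
#' @param n_countries,units_per_country Admin hierarchy sizes.
#' @param n_subpixel_units Number of deliberately sub-pixel units added to
#'   exercise merging (default 1).
#' @param beta0 Intercept of the log-density model (log persons per cell).
#' @param betas Named coefficients on the normalised covariates
#'   (`settlement`, `nightlights`, `elevation`, `dist_road`).
#' @param sigma Standard deviation of the cell-level log-normal noise.
#' @param growth_range Range from which per-unit annual growth rates are
#'   drawn (1/year).
#' @param year1,year2 Decimal census dates.
#' @param prevalence_steepness,prevalence_shift Logistic transform of the
#'   smooth prevalence field.
#' @param n_hotspot_units Units hosting conflict events.
#' @param event_mean Poisson mean of events per hotspot unit and year.
#' @param event_years Years carried by events.
#' @param poisson_truth If TRUE the true surface is a Poisson draw from the
#'   intensity instead of the intensity itself (realism variant; exact
#'   conservation checks use the default FALSE).
#' @return A `world_config`.
#' @export
world_config <- function(seed,
                         extent = c(0, 0, 1, 1),
                         cell_size = 0.01,
                         n_countries = 4,
                         units_per_country = 25,
                         n_subpixel_units = 1,
                         beta0 = 3,
                         betas = c(settlement = 1.5, nightlights = 0.8,
                                   elevation = -0.5, dist_road = -0.8),
                         sigma = 0.2,
                         growth_range = c(-0.02, 0.05),
                         year1 = 2000,
                         year2 = 2010,
                         prevalence_steepness = 6,
                         prevalence_shift = -2,
                         n_hotspot_units = 5,
                         event_mean = 8,
                         event_years = c(2000, 2012, 2014),
                         poisson_truth = FALSE) {
  if (missing(seed)) stop("world_config requires a seed", call. = FALSE)
  stopifnot(sigma >= 0, units_per_country >= 1, n_countries >= 1)
  structure(as.list(environment()), class = "world_config")
}

# box-blurred uniform noise rescaled to [0, 1]; the smoothing radius is in
# cells
smooth_field <- function(nr, nc, passes = 20) {
  m <- matrix(stats::runif(nr * nc), nr, nc)
  for (k in seq_len(passes)) {
    up <- m[c(1, seq_len(nr - 1)), ]; dn <- m[c(seq_len(nr - 1) + 1, nr), ]
    lf <- m[, c(1, seq_len(nc - 1))]; rt <- m[, c(seq_len(nc - 1) + 1, nc)]
    m <- (m + up + dn + lf + rt) / 5
  }
  (m - min(m)) / (max(m) - min(m))
}

#' Simulate administrative units as a clipped Voronoi partition
#'
#' Seeds one point per unit inside the extent and takes the Voronoi
#' tessellation clipped to it, so units partition the extent exactly.
#' Countries are unions of the unit tiles whose seeds are nearest each
#' country seed, so units also partition countries. Optionally a tight
#' cluster of satellite seeds is planted around a cell corner so that its
#' centre tile is guaranteed smaller than a pixel, exercising sub-pixel
#' merging downstream.
#'
#' @param cfg A [world_config()].
#' @return List with `polygons` ([polygon_frame()]), `admin` (admin-ID
#'   raster), `grid`, `units` (tibble `unit_id`, `country_id`), `land`
#'   (all-ones binary raster).
#' @export
simulate_admin_units <- function(cfg) {
  set.seed(cfg$seed)
  ext <- cfg$extent
  grid <- define_mastergrid(ext, cfg$cell_size)
  n <- cfg$n_countries * cfg$units_per_country
  w <- ext[3] - ext[1]; h <- ext[4] - ext[2]
  margin <- 0.02
  sx <- ext[1] + (margin + (1 - 2 * margin) * stats::runif(n)) * w
  sy <- ext[2] + (margin + (1 - 2 * margin) * stats::runif(n)) * h
  cx <- ext[1] + stats::runif(cfg$n_countries) * w
  cy <- ext[2] + stats::runif(cfg$n_countries) * h
  if (cfg$n_subpixel_units > 0) {
    s <- cfg$cell_size
    for (k in seq_len(cfg$n_subpixel_units)) {
      # near a cell corner well inside the extent; satellites at 0.4 cells pin
      # the centre tile inside a square of circumradius ~0.28 cells, too small
      # to capture a cell centre (all >= ~0.56 cells away). The small offsets
      # keep satellite bisectors off exact cell centres.
      corner_x <- ext[1] + round((0.2 + 0.55 * (k - 1) / max(1, cfg$n_subpixel_units)) * w / s) * s +
        0.0731 * s
      corner_y <- ext[2] + round(0.3 * h / s) * s + 0.0293 * s
      d <- 0.4 * s
      sx <- c(sx, corner_x, corner_x + d, corner_x - d, corner_x, corner_x)
      sy <- c(sy, corner_y, corner_y, corner_y, corner_y + d, corner_y - d)
    }
  }
  n_all <- length(sx)
  if (n_all == 1L) {
    # a single unit is the whole extent; nothing to tessellate
    polygons <- polygon_frame(1, list(cbind(c(ext[1], ext[3], ext[3], ext[1]),
                                            c(ext[2], ext[2], ext[4], ext[4]))))
  } else {
    dd <- deldir::deldir(sx, sy, rw = c(ext[1], ext[3], ext[2], ext[4]))
    tiles <- deldir::tile.list(dd)
    polygons <- polygon_frame(
      id = seq_len(n_all),
      geometry = lapply(tiles, function(t) cbind(t$x, t$y))
    )
  }
  country <- vapply(seq_len(n_all), function(i) {
    which.min((sx[i] - cx)^2 + (sy[i] - cy)^2)
  }, integer(1))
  admin <- rasterize_admin_units(polygons, grid)
  land <- grid_raster(grid, 1, "binary")
  list(polygons = polygons, admin = admin, grid = grid,
       units = tibble::tibble(unit_id = seq_len(n_all),
                              country_id = country,
                              seed_lon = sx, seed_lat = sy),
       land = land)
}

#' Simulate a covariate stack over a toy world
#'
#' Produces one layer of each kind the pipeline consumes: a smooth elevation
#' field (metres) and its slope, clustered binary settlement blobs,
#' night-lights radiance decaying with distance from settlement (plus
#' noise), a nine-class categorical land cover, and great-circle distance to
#' a random toy road line.
#'
#' @param cfg A [world_config()].
#' @param world Output of [simulate_admin_units()].
#' @return A [covariate_stack()].
#' @export
simulate_covariates <- function(cfg, world) {
  set.seed(cfg$seed + 1L)
  g <- world$grid
  nr <- g$n_rows; nc <- g$n_cols
  elev_m <- smooth_field(nr, nc) * 1000
  elevation <- grid_raster(g, elev_m, "continuous")
  slope <- slope_from_dem(elevation)

  # settlement blobs around cluster centres
  n_clust <- max(3L, round(nr * nc / 2000))
  ctr <- cbind(sample.int(nr, n_clust, replace = TRUE),
               sample.int(nc, n_clust, replace = TRUE))
  radius <- pmax(2, stats::rpois(n_clust, 4))
  sett <- matrix(0, nr, nc)
  rows <- row(sett); cols <- col(sett)
  for (i in seq_len(n_clust)) {
    sett[(rows - ctr[i, 1])^2 + (cols - ctr[i, 2])^2 <= radius[i]^2] <- 1
  }
  settlement <- grid_raster(g, sett, "binary")

  # nightlights: monotone in proximity to settlement, with noise
  dcell <- matrix(Inf, nr, nc)
  sc <- which(sett == 1)
  scr <- ((sc - 1L) %% nr) + 1L; scc <- ((sc - 1L) %/% nr) + 1L
  for (i in seq_along(sc)) {
    dcell <- pmin(dcell, sqrt((rows - scr[i])^2 + (cols - scc[i])^2))
  }
  nl <- 60 * exp(-dcell / 6) + matrix(stats::rnorm(nr * nc, 0, 0.5), nr, nc)
  nightlights <- grid_raster(g, pmax(nl, 0), "continuous")

  # nine-class land cover from elevation bands, settlement burnt in
  q <- stats::quantile(elev_m, probs = seq(0, 1, length.out = 9))
  lc <- matrix(findInterval(elev_m, q[-c(1, 9)]) + 1, nr, nc)
  lc[lc > 9] <- 9
  lc[sett == 1] <- 6
  landcover <- grid_raster(g, lc, "categorical")

  # a toy road: random west-east polyline, priority 10
  ext <- grid_extent(g)
  xs <- seq(ext["west"], ext["east"], length.out = 6)
  ys <- stats::runif(6, ext["south"] + 0.1 * (ext["north"] - ext["south"]),
                     ext["north"] - 0.1 * (ext["north"] - ext["south"]))
  road <- line_frame(list(cbind(xs, ys)), priority = 10, name = "toy trunk")
  road_r <- priority_rasterize(road, g)
  road_bin <- binary_extract(road_r, classes = 8:30)
  dist_road <- distance_to_feature(road_bin)

  covariate_stack(list(
    elevation = elevation, slope = slope, settlement = settlement,
    nightlights = nightlights, landcover = landcover, dist_road = dist_road
  ))
}

# min-max normalise a matrix, ignoring NA
norm01 <- function(m) {
  lo <- min(m, na.rm = TRUE); hi <- max(m, na.rm = TRUE)
  if (hi == lo) return(m * 0)
  (m - lo) / (hi - lo)
}

#' Simulate the true population surface and two-date census
#'
#' The per-cell intensity is `lambda = exp(beta0 + sum(beta_i * cov_i) +
#' eps)` with `eps ~ N(0, sigma^2)` on normalised covariates; the true cell
#' population is the intensity itself (an expected-value surface, so zonal
#' conservation checks are exact; set `poisson_truth = TRUE` in the config
#' for a sampled variant). Unit counts at the first census date are exact
#' zonal sums of the truth; second-date counts apply a per-unit exponential
#' growth rate drawn from the configured range.
#'
#' @param cfg A [world_config()].
#' @param world Output of [simulate_admin_units()].
#' @param stack Output of [simulate_covariates()].
#' @return List with `truth` (population `grid_raster` at `year1`),
#'   `census` (tibble `unit_id`, `parent_id`, `P1`, `year1`, `P2`, `year2`),
#'   `growth` (tibble `unit_id`, `r_true`).
#' @export
simulate_population <- function(cfg, world, stack) {
  set.seed(cfg$seed + 2L)
  g <- world$grid
  b <- cfg$betas
  eta <- cfg$beta0 +
    b[["settlement"]] * stack$settlement$values +
    b[["nightlights"]] * norm01(stack$nightlights$values) +
    b[["elevation"]] * norm01(stack$elevation$values) +
    b[["dist_road"]] * norm01(stack$dist_road$values)
  if (cfg$sigma > 0) {
    eta <- eta + matrix(stats::rnorm(length(eta), 0, cfg$sigma),
                        nrow(eta), ncol(eta))
  }
  lambda <- exp(eta)
  truth_vals <- if (cfg$poisson_truth) {
    matrix(stats::rpois(length(lambda), lambda), nrow(lambda), ncol(lambda))
  } else lambda
  truth <- grid_raster(g, truth_vals, "continuous")
  # every unit gets a record; sub-pixel units have zero cells, hence a zero
  # zonal sum, and are resolved by merge_subpixel_units downstream
  ids <- world$units$unit_id
  zone <- as.vector(world$admin$values)
  tv <- as.vector(truth_vals)
  P1 <- vapply(ids, function(u) sum(tv[!is.na(zone) & zone == u]), numeric(1))
  r_true <- stats::runif(length(ids), cfg$growth_range[1], cfg$growth_range[2])
  dt <- cfg$year2 - cfg$year1
  census <- tibble::tibble(
    unit_id = ids,
    parent_id = world$units$country_id[match(ids, world$units$unit_id)],
    P1 = P1, year1 = cfg$year1,
    P2 = P1 * exp(r_true * dt), year2 = cfg$year2
  )
  list(truth = truth, census = census,
       growth = tibble::tibble(unit_id = ids, r_true = r_true))
}

#' Simulate a prevalence field and conflict events
#'
#' Prevalence is the logistic transform of a smooth random field, so it lies
#' in (0, 1) everywhere. Events follow an inhomogeneous point process
#' concentrated in hotspot units: per hotspot unit and year the event count
#' is Poisson with the configured mean, and locations are uniform within
#' the unit's cells.
#'
#' @param cfg A [world_config()].
#' @param world Output of [simulate_admin_units()].
#' @return List with `prevalence` (`grid_raster` in \[0, 1\]) and `events`
#'   (an [event_set()]).
#' @export
simulate_prevalence_and_events <- function(cfg, world) {
  set.seed(cfg$seed + 3L)
  g <- world$grid
  f <- smooth_field(g$n_rows, g$n_cols)
  prev <- stats::plogis(cfg$prevalence_steepness * (f - 0.5) +
                          cfg$prevalence_shift)
  prevalence <- grid_raster(g, prev, "continuous")
  ids <- admin_unit_ids(world$admin)
  hot <- utils::head(ids, cfg$n_hotspot_units)
  lon <- lat <- yr <- numeric(0)
  if (cfg$event_mean > 0) {
    ext <- grid_extent(g)
    for (u in hot) {
      cells <- which(!is.na(world$admin$values) & world$admin$values == u)
      if (!length(cells)) next
      for (y in cfg$event_years) {
        k <- stats::rpois(1, cfg$event_mean)
        if (k == 0) next
        pick <- sample(cells, k, replace = TRUE)
        pr <- ((pick - 1L) %% g$n_rows) + 1L
        pc <- ((pick - 1L) %/% g$n_rows) + 1L
        lon <- c(lon, ext["west"] + (pc - stats::runif(k)) * g$cell_size)
        lat <- c(lat, ext["north"] - (pr - stats::runif(k)) * g$cell_size)
        yr <- c(yr, rep(y, k))
      }
    }
  }
  list(prevalence = prevalence, events = event_set(lon, lat, yr))
}

#' Generate a complete synthetic world
#'
#' Bundles admin units, covariates, the true population surface, the
#' two-date census table, the prevalence field and the event set, all
#' deterministic under the config seed.
#'
#' @param cfg A [world_config()].
#' @return A `synthetic_world` list: `config`, `grid`, `polygons`, `admin`,
#'   `units`, `land`, `stack`, `truth`, `census`, `growth`, `prevalence`,
#'   `events`.
#' @export
simulate_world <- function(cfg) {
  world <- simulate_admin_units(cfg)
  stack <- simulate_covariates(cfg, world)
  popn <- simulate_population(cfg, world, stack)
  pe <- simulate_prevalence_and_events(cfg, world)
  structure(
    c(list(config = cfg), world,
      list(stack = stack, truth = popn$truth, census = popn$census,
           growth = popn$growth, prevalence = pe$prevalence,
           events = pe$events)),
    class = "synthetic_world"
  )
}

#' Write a synthetic world to a directory
#'
#' Rasters go out as ESRI ASCII grids, vector features as GeoJSON, the
#' census as CSV, and the generating parameters as a JSON manifest.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ascii_grid(world$admin, file.path(dir, "admin_id.asc"))
  write_ascii_grid(world$truth, file.path(dir, "true_population.asc"))
  write_ascii_grid(world$prevalence, file.path(dir, "prevalence.asc"))
  for (nm in names(world$stack)) {
    write_ascii_grid(world$stack[[nm]], file.path(dir, paste0("cov_", nm, ".asc")))
  }
  write_polygons_geojson(world$polygons, file.path(dir, "admin_units.geojson"))
  write_events_geojson(world$events, file.path(dir, "events.geojson"))
  write_census_csv(world$census, file.path(dir, "census.csv"))
  write_grid_config(world$grid, file.path(dir, "mastergrid.json"))
  cfg <- world$config
  cfg$betas <- as.list(cfg$betas)
  jsonlite::write_json(unclass(cfg), file.path(dir, "world_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
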
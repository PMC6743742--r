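#' Pipeline configuration
#'
#' A single human-readable configuration for the end-to-end run. Every
#' numeric default of the workflow is surfaced as a named key: the
#' prevalence threshold (0.10), conflict zone size (9 km) and minimum event
#' count (2), the retained road classes (8-30) and intersection classes
#' (8-17), and the protected-area point buffer (70 m).
#'
#' @param out_dir Output directory.
#' @param seed Integer seed used by the simulate and random-forest stages.
#' @param stages Character vector of enabled stages, a subset of
#'   `c("simulate", "census", "covariates", "dasymetric", "applications")`,
#'   executed in dependency order.
#' @param world A [world_config()] for the simulate stage.
#' @param years Target years of the census series.
#' @param target_year Year whose interpolated counts are redistributed.
#' @param prevalence_threshold At-risk prevalence cut (fraction).
#' @param zone_km,min_events Conflict-zone parameters.
#' @param retain_classes,intersection_classes Road class ranges.
#' @param pa_buffer_m Protected-area point buffer (metres).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed,
                            stages = c("simulate", "census", "covariates",
                                       "dasymetric", "applications"),
                            world = world_config(seed = seed),
                            years = 2000:2020,
                            target_year = 2000,
                            prevalence_threshold = 0.10,
                            zone_km = 9,
                            min_events = 2,
                            retain_classes = c(8, 30),
                            intersection_classes = c(8, 17),
                            pa_buffer_m = 70) {
  known <- c("simulate", "census", "covariates", "dasymetric", "applications")
  if (!all(stages %in% known)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "),
         call. = FALSE)
  }
  if (any(c("simulate", "dasymetric") %in% stages) && missing(seed)) {
    stop("a seed is required when the simulate or dasymetric stage is enabled",
         call. = FALSE)
  }
  if (missing(seed)) seed <- NA_integer_
  structure(as.list(environment())[known_config_fields()],
            class = "pipeline_config")
}

known_config_fields <- function() {
  c("out_dir", "seed", "stages", "world", "years", "target_year",
    "prevalence_threshold", "zone_km", "min_events", "retain_classes",
    "intersection_classes", "pa_buffer_m")
}

#' Read a written synthetic world back from disk
#'
#' @param dir Directory produced by [write_world()].
#' @return A `synthetic_world` (without the generating truth parameters).
#' @export
read_world <- function(dir) {
  kinds <- c(elevation = "continuous", slope = "continuous",
             settlement = "binary", nightlights = "continuous",
             landcover = "categorical", dist_road = "continuous")
  stack <- covariate_stack(lapply(stats::setNames(names(kinds), names(kinds)),
    function(nm) {
      read_ascii_grid(file.path(dir, paste0("cov_", nm, ".asc")), kinds[[nm]])
    }))
  admin <- read_ascii_grid(file.path(dir, "admin_id.asc"), "categorical")
  grid <- admin$grid
  census <- read_census_csv(file.path(dir, "census.csv"))
  units <- dplyr::distinct(census, unit_id = .data$unit_id,
                           country_id = .data$parent_id)
  structure(list(
    grid = grid, admin = admin, stack = stack, census = census,
    polygons = read_polygons_geojson(file.path(dir, "admin_units.geojson")),
    truth = read_ascii_grid(file.path(dir, "true_population.asc")),
    prevalence = read_ascii_grid(file.path(dir, "prevalence.asc")),
    events = read_events_geojson(file.path(dir, "events.geojson")),
    units = units,
    land = grid_raster(grid, 1, "binary")
  ), class = "synthetic_world")
}

#' Region (country) raster from a unit raster
#'
#' Relabels an admin-ID raster at the parent level using a unit-to-country
#' lookup, for regional reporting.
#'
#' @param admin Admin-ID `grid_raster`.
#' @param units Tibble with columns `unit_id`, `country_id`.
#' @return Categorical `grid_raster` of country IDs.
#' @export
country_raster <- function(admin, units) {
  idx <- match(admin$values, units$unit_id)
  vals <- matrix(units$country_id[idx], admin$grid$n_rows, admin$grid$n_cols)
  grid_raster(admin$grid, vals, "categorical")
}

stage_log <- function(stage, t0) {
  message(sprintf("[gridpop] %-12s %6.2f s", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the configured pipeline stages
#'
#' Executes the enabled stages in dependency order (simulate -> census ->
#' covariates -> dasymetric -> applications), writing artefacts under
#' `out_dir` and a JSON manifest listing produced files with MD5 digests,
#' the parameters used, and the per-unit conservation audit. Rerunning with
#' an identical config reproduces identical outputs. A stage whose upstream
#' artefacts are neither enabled nor already on disk is rejected by name.
#'
#' @param cfg A [pipeline_config()].
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(parameters = list(
    seed = cfg$seed, stages = cfg$stages, years = range(cfg$years),
    target_year = cfg$target_year,
    prevalence_threshold = cfg$prevalence_threshold,
    zone_km = cfg$zone_km, min_events = cfg$min_events,
    retain_classes = cfg$retain_classes,
    intersection_classes = cfg$intersection_classes,
    pa_buffer_m = cfg$pa_buffer_m
  ), outputs = list())
  if (length(cfg$stages) == 0L) {
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(manifest))
  }
  world_dir <- file.path(cfg$out_dir, "world")
  world <- NULL
  add_output <- function(stage, path) {
    manifest$outputs[[length(manifest$outputs) + 1]] <<- list(
      stage = stage, path = path,
      md5 = unname(tools::md5sum(path))
    )
  }
  need_world <- function(stage) {
    if (!is.null(world)) return(invisible(NULL))
    if (!file.exists(file.path(world_dir, "admin_id.asc"))) {
      stop(sprintf("stage '%s' needs the simulate stage (or an existing world directory)",
                   stage), call. = FALSE)
    }
    world <<- read_world(world_dir)
    invisible(NULL)
  }

  if ("simulate" %in% cfg$stages) {
    t0 <- as.numeric(Sys.time())
    world <- simulate_world(cfg$world)
    write_world(world, world_dir)
    for (f in list.files(world_dir, full.names = TRUE)) add_output("simulate", f)
    stage_log("simulate", t0)
  }

  series <- NULL
  merged <- NULL
  if ("census" %in% cfg$stages) {
    t0 <- as.numeric(Sys.time())
    need_world("census")
    merged <- merge_subpixel_units(world$census, world$admin, world$polygons)
    series <- interpolate_census_series(merged$records, years = cfg$years)
    p1 <- file.path(cfg$out_dir, "census_series.csv")
    readr::write_csv(series, p1); add_output("census", p1)
    p2 <- file.path(cfg$out_dir, "merge_mapping.csv")
    readr::write_csv(merged$mapping, p2); add_output("census", p2)
    stage_log("census", t0)
  }

  areas <- NULL
  if ("covariates" %in% cfg$stages) {
    t0 <- as.numeric(Sys.time())
    need_world("covariates")
    areas <- pixel_area_grid(world$grid)
    p <- file.path(cfg$out_dir, "pixel_area.asc")
    write_ascii_grid(areas, p); add_output("covariates", p)
    stage_log("covariates", t0)
  }

  audit <- NULL
  pop <- NULL
  if ("dasymetric" %in% cfg$stages) {
    t0 <- as.numeric(Sys.time())
    need_world("dasymetric")
    if (is.null(series)) {
      stop("stage 'dasymetric' needs the census stage", call. = FALSE)
    }
    if (is.null(areas)) {
      stop("stage 'dasymetric' needs the covariates stage", call. = FALSE)
    }
    admin <- world$admin
    summaries <- zonal_covariate_summary(world$stack, admin, areas)
    counts <- dplyr::filter(series, .data$year == cfg$target_year) |>
      dplyr::select(unit_id = "unit_id", count = "count")
    model <- fit_density_model(summaries, counts, seed = cfg$seed)
    w <- predict_weight_surface(model, world$stack, world$land)
    red <- redistribute_counts(w, admin, counts)
    pop <- red$population; audit <- red$audit
    p1 <- file.path(cfg$out_dir, "population.asc")
    write_ascii_grid(pop, p1); add_output("dasymetric", p1)
    p2 <- file.path(cfg$out_dir, "conservation_audit.csv")
    readr::write_csv(audit, p2); add_output("dasymetric", p2)
    manifest$conservation <- list(
      n_units = nrow(audit),
      n_violations = sum(audit$output_sum != audit$input_count),
      max_abs_error = max(abs(audit$output_sum - audit$input_count))
    )
    stage_log("dasymetric", t0)
  }

  if ("applications" %in% cfg$stages) {
    t0 <- as.numeric(Sys.time())
    need_world("applications")
    if (is.null(pop)) {
      stop("stage 'applications' needs the dasymetric stage", call. = FALSE)
    }
    regions <- country_raster(world$admin, world$units)
    risk <- population_at_risk(pop, world$prevalence, regions,
                               threshold = cfg$prevalence_threshold)
    p1 <- file.path(cfg$out_dir, "population_at_risk.csv")
    readr::write_csv(risk, p1); add_output("applications", p1)
    flagged <- conflict_zones(world$events, world$grid,
                              zone_km = cfg$zone_km,
                              min_events = cfg$min_events)
    p2 <- file.path(cfg$out_dir, "conflict_zones.asc")
    write_ascii_grid(flagged, p2); add_output("applications", p2)
    prox <- population_near_conflict(pop, flagged, regions)
    p3 <- file.path(cfg$out_dir, "population_near_conflict.csv")
    readr::write_csv(prox, p3); add_output("applications", p3)
    stage_log("applications", t0)
  }

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
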
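#' Annualised exponential growth rate between two censuses
#'
#' `r = ln(P2 / P1) / t`, the constant per-year exponential rate linking two
#' census counts taken `t` years apart. Units with a zero count at either
#' date have no defined rate; they are kept alive with `r = 0` and a warning
#' rather than dropped.
#'
#' @param P1 Population count at the earlier census (persons).
#' @param P2 Population count at the latest census (persons).
#' @param t Years between the two censuses (> 0); decimal years are fine.
#' @return Annualised growth rate (1/year), vectorised over inputs.
#' @examples
#' annual_growth_rate(100, 200, 10) # ln(2)/10
#' @export
annual_growth_rate <- function(P1, P2, t) {
  if (any(t <= 0)) stop("census interval t must be positive", call. = FALSE)
  r <- numeric(length(P1))
  bad <- P1 <= 0 | P2 <= 0
  if (any(bad)) {
    warning(sprintf("%d unit(s) with non-positive counts: growth rate set to 0",
                    sum(bad)), call. = FALSE)
  }
  tt <- rep_len(t, length(P1))
  r[!bad] <- log(P2[!bad] / P1[!bad]) / tt[!bad]
  r
}

#' Project a census count forward or backward
#'
#' `Px = P2 * exp(r * t)`: the population estimate `t` years after the latest
#' census (negative `t` interpolates between the two censuses).
#'
#' @param P2 Count at the latest census (persons).
#' @param r Annualised growth rate (1/year).
#' @param t Years from the latest census (may be negative).
#' @return Projected count (persons), always non-negative.
#' @export
project_population <- function(P2, r, t) {
  if (any(!is.finite(r))) stop("growth rate must be finite", call. = FALSE)
  P2 * exp(r * t)
}

#' Interpolate a two-date census record to an annual series
#'
#' Applies the unit's exponential growth rate to produce one count per target
#' year. The series reproduces `P2` at `year2` exactly and `P1` at `year1`
#' (up to floating point).
#'
#' @param records Tibble/data frame with columns `unit_id`, `P1`, `year1`,
#'   `P2`, `year2` (and optionally `r` to override the own-pair rate, as set
#'   by [fallback_growth_rate()]).
#' @param years Integer vector of target years (default 2000:2020).
#' @return Long tibble `unit_id`, `year`, `count`.
#' @export
interpolate_census_series <- function(records, years = 2000:2020) {
  stopifnot(all(c("unit_id", "P1", "year1", "P2", "year2") %in% names(records)))
  if (any(records$year2 <= records$year1)) {
    stop("year2 must be after year1 for every record", call. = FALSE)
  }
  if (any(records$P1 < 0 | records$P2 < 0)) {
    stop("census counts must be non-negative", call. = FALSE)
  }
  recs <- tibble::as_tibble(records)
  if (!"r" %in% names(recs)) {
    recs$r <- annual_growth_rate(recs$P1, recs$P2, recs$year2 - recs$year1)
  }
  tidyr::crossing(recs, year = years) |>
    dplyr::mutate(count = project_population(.data$P2, .data$r,
                                             .data$year - .data$year2)) |>
    dplyr::select("unit_id", "year", "count") |>
    dplyr::arrange(.data$unit_id, .data$year)
}

#' Inherit growth rates from a coarser administrative level
#'
#' Units whose two census counts cannot be matched (e.g. boundary changes)
#' receive the growth rate computed at their parent (state/province or
#' district) level; units with a valid pair of their own are untouched.
#'
#' @param records Tibble of census records (`unit_id`, `parent_id`, `P1`,
#'   `year1`, `P2`, `year2`). A record needs fallback when `P1` or `P2` is
#'   missing (`NA`).
#' @param parents Tibble of parent-level records (`unit_id`, `P1`, `year1`,
#'   `P2`, `year2`), one per parent.
#' @return `records` with columns `r` (1/year) and `r_source`
#'   (`"own"`/`"parent"`) added; records needing fallback use the parent's
#'   `P2`-relative rate applied to their own latest available count.
#' @export
fallback_growth_rate <- function(records, parents) {
  recs <- tibble::as_tibble(records)
  needs <- is.na(recs$P1) | is.na(recs$P2)
  par_r <- tibble::tibble(
    parent_id = parents$unit_id,
    r_parent = annual_growth_rate(parents$P1, parents$P2,
                                  parents$year2 - parents$year1)
  )
  orphan <- needs & !(recs$parent_id %in% par_r$parent_id)
  if (any(orphan)) {
    stop("no parent record for unit(s): ",
         paste(recs$unit_id[orphan], collapse = ", "), call. = FALSE)
  }
  own_r <- rep(NA_real_, nrow(recs))
  own_r[!needs] <- annual_growth_rate(recs$P1[!needs], recs$P2[!needs],
                                      recs$year2[!needs] - recs$year1[!needs])
  recs |>
    dplyr::left_join(par_r, by = "parent_id") |>
    dplyr::mutate(
      r = ifelse(needs, .data$r_parent, own_r),
      r_source = ifelse(needs, "parent", "own")
    ) |>
    dplyr::select(-"r_parent")
}

#' Merge administrative units smaller than a pixel
#'
#' Units present in the census table but absent from the rasterised admin
#' layer (sub-pixel units) are removed and their counts at both census dates
#' added to the unit owning the cell at the lost unit's representative point,
#' so national totals are conserved exactly. If that point falls on no-data,
#' the nearest unit-bearing cell absorbs instead (reported in the mapping).
#'
#' @param records Census tibble (`unit_id`, `P1`, `P2`, ...).
#' @param admin Admin-ID `grid_raster` from [rasterize_admin_units()].
#' @param polygons [polygon_frame()] providing geometry for absorbed units.
#' @return List with `records` (adjusted table) and `mapping` (tibble
#'   `absorbed_id`, `absorbing_id`, `via_nearest`).
#' @export
merge_subpixel_units <- function(records, admin, polygons) {
  recs <- tibble::as_tibble(records)
  present <- admin_unit_ids(admin)
  lost <- setdiff(recs$unit_id, present)
  mapping <- tibble::tibble(absorbed_id = numeric(), absorbing_id = numeric(),
                            via_nearest = logical())
  if (length(lost) == 0L) return(list(records = recs, mapping = mapping))
  g <- admin$grid
  ext <- grid_extent(g)
  for (uid in lost) {
    ring <- polygons$geometry[[match(uid, polygons$id)]]
    if (is.null(ring)) {
      stop("no polygon available for sub-pixel unit ", uid, call. = FALSE)
    }
    pt <- representative_point(ring)
    cc <- pmin(pmax(floor((pt[1] - ext["west"]) / g$cell_size) + 1, 1), g$n_cols)
    rr <- pmin(pmax(floor((ext["north"] - pt[2]) / g$cell_size) + 1, 1), g$n_rows)
    owner <- admin$values[rr, cc]
    via_nearest <- FALSE
    wc <- attr(admin, "water_code")
    if (is.na(owner) || (!is.null(wc) && owner == wc) || !(owner %in% present)) {
      # representative pixel carries no unit: absorb into the nearest one
      cand <- which(matrix(admin$values %in% present, g$n_rows, g$n_cols),
                    arr.ind = TRUE)
      d2 <- (cand[, 1] - rr)^2 + (cand[, 2] - cc)^2
      k <- which.min(d2)
      owner <- admin$values[cand[k, 1], cand[k, 2]]
      via_nearest <- TRUE
      message(sprintf("unit %s: representative point on no-data; absorbed into nearest unit %s",
                      format(uid), format(owner)))
    }
    i_lost <- match(uid, recs$unit_id)
    i_abs <- match(owner, recs$unit_id)
    recs$P1[i_abs] <- recs$P1[i_abs] + recs$P1[i_lost]
    recs$P2[i_abs] <- recs$P2[i_abs] + recs$P2[i_lost]
    recs <- recs[-i_lost, ]
    mapping <- dplyr::bind_rows(mapping,
      tibble::tibble(absorbed_id = uid, absorbing_id = owner,
                     via_nearest = via_nearest))
  }
  list(records = recs, mapping = mapping)
}
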
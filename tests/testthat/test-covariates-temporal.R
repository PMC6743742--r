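test_that("DMSP compositing averages two satellites and zeroes gaps", {
  g <- toy_grid(2, 2)
  a <- grid_raster(g, matrix(c(10, 5, NA, NA), 2, 2), "continuous")
  b <- grid_raster(g, matrix(c(30, 5, 2, NA), 2, 2), "continuous")
  out <- dmsp_annual_composite(a, b)
  expect_equal(out$values[1, 1], 20)   # (10 + 30) / 2
  expect_equal(out$values[2, 1], 5)    # mean of equals
  expect_equal(out$values[1, 2], 2)    # single coverage passes through
  expect_equal(out$values[2, 2], 0)    # polar no-coverage becomes zero

  # commutative in its two inputs
  expect_identical(dmsp_annual_composite(a, b)$values,
                   dmsp_annual_composite(b, a)$values)

  # single-satellite year: identity plus the polar-zero rule
  solo <- dmsp_annual_composite(a)
  expect_equal(solo$values[1, 1], 10)
  expect_equal(solo$values[1, 2], 0)

  g3 <- toy_grid(3, 3)
  expect_error(dmsp_annual_composite(a, grid_raster(g3, 1, "continuous")),
               "co-registered")
})

test_that("VIIRS compositing attenuates by months observed", {
  g <- toy_grid(2, 2)
  rad <- lapply(1:12, function(m) grid_raster(g, 7, "continuous"))
  obs <- lapply(1:12, function(m) grid_raster(g, 1, "continuous"))
  st <- viirs_stack(2013, rad, obs)
  expect_true(all(viirs_annual_composite(st)$values == 7))

  # radiances (2, 4, 6) in 3 observed months of 12 -> 12 / 3 = 4
  rad2 <- lapply(1:12, function(m) {
    grid_raster(g, c(2, 4, 6, 0)[min(m, 4)], "continuous")
  })
  obs2 <- lapply(1:12, function(m) grid_raster(g, as.numeric(m <= 3),
                                               "continuous"))
  expect_true(all(viirs_annual_composite(viirs_stack(2013, rad2, obs2))$values == 4))

  # partial years carry nine months
  expect_s3_class(viirs_stack(2012, rad[1:9], obs[1:9]), "viirs_stack")
  expect_error(viirs_stack(2013, rad[1:8], obs[1:8]), "12 monthly|9")
  expect_error(viirs_stack(2013, rad, obs[1:9]), "differ")

  none <- lapply(1:12, function(m) grid_raster(g, 0, "continuous"))
  expect_error(viirs_annual_composite(viirs_stack(2013, rad, none)),
               "no cell")
})

test_that("an unobserved cell is filled from its surrounding values", {
  g <- toy_grid(3, 3)
  rad <- lapply(1:12, function(m) grid_raster(g, 5, "continuous"))
  obs_m <- matrix(1, 3, 3); obs_m[2, 2] <- 0
  obs <- lapply(1:12, function(m) grid_raster(g, obs_m, "continuous"))
  out <- viirs_annual_composite(viirs_stack(2014, rad, obs))
  expect_equal(out$values[2, 2], 5)   # one focal-mean pass of constant 5
  expect_true(all(out$values == 5))
  # without filling the cell stays no-data
  raw <- viirs_annual_composite(viirs_stack(2014, rad, obs), fill = FALSE)
  expect_true(is.na(raw$values[2, 2]))
})

test_that("the VIIRS compositor matches a brute-force oracle pre-fill", {
  set.seed(41)
  g <- mastergrid(0.0625, 0, 1, 16, 16)
  rad <- lapply(1:12, function(m) {
    grid_raster(g, matrix(runif(256, 0, 50), 16, 16), "continuous")
  })
  obs <- lapply(1:12, function(m) {
    grid_raster(g, matrix(rbinom(256, 3, 0.6), 16, 16), "continuous")
  })
  out <- viirs_annual_composite(viirs_stack(2015, rad, obs), fill = FALSE)
  for (rr in seq_len(16)) for (cc in seq_len(16)) {
    seen <- vapply(1:12, function(m) obs[[m]]$values[rr, cc] > 0, logical(1))
    expected <- if (!any(seen)) NA_real_ else {
      sum(vapply(which(seen), function(m) rad[[m]]$values[rr, cc],
                 numeric(1))) / sum(seen)
    }
    expect_equal(out$values[rr, cc], expected)
  }
})

test_that("the protected-area series is cumulative with 72 + 36 rasters", {
  g <- toy_grid(8, 8, cell = 0.125)
  pa <- protected_areas(
    geometry = list(square_ring(0.05, 0.55, 0.45, 0.95),
                    square_ring(0.55, 0.05, 0.95, 0.45),
                    square_ring(0.05, 0.05, 0.45, 0.45),
                    c(0.75, 0.75)),
    designation_year = c(1985, 2010, 2005, 2017),
    iucn_group = c("strict1", "strict1", "other", "other"),
    domain = c("terrestrial", "terrestrial", "marine", "marine"),
    buffer_m = 20000   # wide buffer so the point covers cells at this scale
  )
  out <- wdpa_annual_series(pa, g)
  expect_length(out$premosaic, 72)
  expect_length(out$final, 36)
  expect_equal(sum(grepl("_strict1_terrestrial$", names(out$premosaic))), 18)

  # a 2010 polygon is absent in 2005 and present from 2010 onward
  expect_equal(sum(out$premosaic[["2005_strict1_terrestrial"]]$values[5:8, 5:8]), 0)
  expect_gt(sum(out$premosaic[["2010_strict1_terrestrial"]]$values[5:8, 5:8]), 0)
  expect_gt(sum(out$premosaic[["2017_strict1_terrestrial"]]$values[5:8, 5:8]), 0)
  # pre-2000 designations are in the first year already
  expect_gt(sum(out$premosaic[["2000_strict1_terrestrial"]]$values), 0)

  # monotone growth of every group/domain series
  for (gname in c("strict1", "other")) for (d in c("terrestrial", "marine")) {
    prev <- NULL
    for (y in 2000:2017) {
      cur <- out$premosaic[[sprintf("%d_%s_%s", y, gname, d)]]$values
      if (!is.null(prev)) expect_true(all(cur[prev == 1] == 1))
      prev <- cur
    }
  }

  # the final mosaic is the union of the two domains
  u <- pmax(out$premosaic[["2017_other_terrestrial"]]$values,
            out$premosaic[["2017_other_marine"]]$values)
  expect_identical(out$final[["2017_other"]]$values, u)

  expect_error(protected_areas(list(c(0, 0)), 2010, "iucn-1a", "terrestrial"),
               "strict1")
  expect_error(protected_areas(list(c(0, 0)), 2020, "other", "marine"),
               "2017")
})

test_that("point protected areas buffer to cells within the radius", {
  # 0.0005 deg cells (~55 m): a 70 m buffer reaches beyond the centre cell
  g <- mastergrid(0.0005, 0, 0.004, 8, 8)
  pa <- protected_areas(list(c(0.002, 0.002)), 2000, "other", "terrestrial",
                        buffer_m = 70)
  out <- wdpa_annual_series(pa, g, years = 2000)
  covered <- which(out$premosaic[["2000_other_terrestrial"]]$values == 1)
  expect_gt(length(covered), 1)
  r <- out$premosaic[["2000_other_terrestrial"]]
  for (idx in covered) {
    rr <- ((idx - 1) %% 8) + 1; cc <- ((idx - 1) %/% 8) + 1
    expect_lte(haversine_oracle(cell_lon(g)[cc], cell_lat(g)[rr],
                                0.002, 0.002), 70 + 1e-6)
  }
})

test_that("built-settlement fusion follows the stated set algebra", {
  g <- toy_grid(4, 4)
  rb <- function(m) grid_raster(g, matrix(m, 4, 4), "binary")
  set.seed(43)
  ghsl2000 <- rb(rbinom(16, 1, 0.4))
  esa2000 <- rb(rbinom(16, 1, 0.4))
  guf2012 <- rb(rbinom(16, 1, 0.4))
  ghsl2014 <- rb(rbinom(16, 1, 0.4))
  out <- built_settlement_series(ghsl2000, esa2000, guf2012, ghsl2014)
  b <- function(r) r$values == 1
  expect_identical(b(out$year2000),
                   b(ghsl2000) | (b(esa2000) & b(guf2012)))
  expect_identical(b(out$year2012), b(out$year2000) | b(guf2012))
  expect_identical(b(out$year2014), b(guf2012) | b(ghsl2014))

  # an ESA-only pixel missing from GUF 2012 never reaches the 2000 layer
  only_esa <- built_settlement_series(rb(0), rb(1), rb(0), rb(0))
  expect_true(all(only_esa$year2000$values == 0))

  # union supersets
  expect_true(all(b(out$year2012)[b(out$year2000)]))
  expect_true(all(b(out$year2014)[b(guf2012)]))
})
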
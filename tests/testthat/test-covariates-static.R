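test_that("pixel areas are constant along rows and sum to the sphere", {
  earth <- earth_model()
  # 2x2 global grid of 90-degree cells: each cell is a quarter hemisphere
  g2 <- mastergrid(90, -180, 90, 2, 4)
  a2 <- pixel_area_grid(g2, earth)
  expect_equal(a2$values, matrix((pi / 2) * earth$R^2, 2, 4) *
                 matrix(1, 2, 4), tolerance = 1e-12)
  # full-coverage grids at several resolutions telescope to 4*pi*R^2
  for (s in c(30, 10, 5)) {
    g <- mastergrid(s, -180, 90, 180 / s, 360 / s)
    a <- pixel_area_grid(g, earth)
    expect_equal(sum(a$values), 4 * pi * earth$R^2, tolerance = 1e-9)
    expect_true(all(apply(a$values, 1, function(r) all(r == r[1]))))
  }
  # row areas strictly decrease with |latitude| of the row centre
  g <- mastergrid(10, -180, 90, 18, 36)
  rowa <- pixel_area_grid(g, earth)$values[, 1]
  south <- 10:18   # |lat| strictly increasing, no hemispheric ties
  expect_true(all(diff(rowa[south]) < 0))
  expect_equal(rowa[1:9], rev(rowa[south]), tolerance = 1e-9)
})

test_that("slope recovers analytic gradients and respects no-data", {
  earth <- earth_model()
  g <- mastergrid(0.01, 0, 0.03, 5, 5)   # straddles the equator
  # plane rising 1 m per 100 m eastward
  dx <- earth$R * cos(cell_lat(g) * pi / 180) * 0.01 * pi / 180
  z <- outer(seq_len(5), seq_len(5), function(r, c) 0.01 * c * mean(dx))
  slope <- slope_from_dem(grid_raster(g, z, "continuous"), earth)
  expect_equal(slope$values[3, 3], atan(0.01) * 180 / pi, tolerance = 1e-3)
  expect_equal(slope$values[3, 3], 0.5729, tolerance = 1e-3)

  flat <- slope_from_dem(grid_raster(g, 100, "continuous"), earth)
  expect_true(all(flat$values[2:4, 2:4] == 0))
  expect_true(all(is.na(flat$values[1, ])))   # border is no-data

  z[3, 3] <- NA
  holed <- slope_from_dem(grid_raster(g, z, "continuous"), earth)
  expect_true(all(is.na(holed$values[2:4, 2:4])))

  expect_error(slope_from_dem(toy_raster(1:4, 2, 2)), "3 x 3")
})

test_that("the default land-cover aggregation yields nine classes", {
  map <- default_landcover_mapping()
  expect_equal(sort(unique(map$aggregate_code)), 1:9)
  lc <- toy_raster(rep(map$source_code, length.out = 36), 6, 6,
                   kind = "categorical")
  out <- reclassify_landcover(lc)
  expect_equal(sort(unique(as.vector(out$values))), 1:9)
})

test_that("reclassification conserves the histogram and rejects gaps", {
  set.seed(31)
  codes <- c(10, 50, 110, 190, 210)
  lc <- toy_raster(sample(codes, 64, replace = TRUE), 8, 8,
                   kind = "categorical")
  map <- tibble::tibble(source_code = codes, aggregate_code = c(1, 2, 2, 3, 4))
  out <- reclassify_landcover(lc, map)
  for (a in unique(map$aggregate_code)) {
    expect_equal(sum(out$values == a),
                 sum(lc$values %in% map$source_code[map$aggregate_code == a]))
  }
  ident <- tibble::tibble(source_code = codes, aggregate_code = codes)
  expect_identical(reclassify_landcover(lc, ident)$values, lc$values)
  expect_error(reclassify_landcover(lc, map[-1, ]), "10")
})

test_that("binary extraction matches per-cell membership", {
  set.seed(32)
  lc <- toy_raster(sample(1:5, 64, replace = TRUE), 8, 8, kind = "categorical")
  lc$values[3, 3] <- NA
  b <- binary_extract(lc, c(2, 4))
  oracle <- ifelse(is.na(lc$values), NA, as.numeric(lc$values %in% c(2, 4)))
  expect_identical(b$values, oracle)
  expect_true(all(binary_extract(lc, 1:5)$values[!is.na(lc$values)] == 1))
  expect_true(all(binary_extract(lc, 99)$values[!is.na(lc$values)] == 0))
  pres <- binary_extract(lc, c(2, 4), mode = "presence")
  expect_true(all(is.na(pres$values[!is.na(lc$values) &
                                      !(lc$values %in% c(2, 4))])))
  expect_error(binary_extract(lc, numeric(0)), "non-empty")
})

test_that("distance to feature matches an exhaustive haversine oracle", {
  g <- mastergrid(0.1, 0, 1, 9, 9)
  v <- matrix(0, 9, 9); v[4, 6] <- 1
  feat <- grid_raster(g, v, "binary")
  d <- distance_to_feature(feat)
  expect_equal(d$values[4, 6], 0)
  for (rr in c(1, 3, 7, 9)) for (cc in c(1, 5, 9)) {
    expect_equal(d$values[rr, cc],
                 haversine_oracle(cell_lon(g)[cc], cell_lat(g)[rr],
                                  cell_lon(g)[6], cell_lat(g)[4]),
                 tolerance = 1e-9)
  }
  # approaching the feature along its row, distance decreases
  expect_true(all(diff(d$values[4, 1:6]) < 0))
  none <- grid_raster(g, matrix(0, 9, 9), "binary")
  expect_error(distance_to_feature(none), "no feature")
})

test_that("annual climate layers average or sum the twelve months", {
  g <- toy_grid()
  months <- lapply(1:12, function(m) grid_raster(g, m, "continuous"))
  expect_true(all(climate_annual(months, "mean")$values == 6.5))
  expect_true(all(climate_annual(months, "sum")$values == 78))
  const <- lapply(1:12, function(m) grid_raster(g, 3.25, "continuous"))
  expect_true(all(climate_annual(const, "mean")$values == 3.25))
  expect_true(all(climate_annual(const, "sum")$values == 39))
  months[[5]]$values[2, 2] <- NA
  expect_true(is.na(climate_annual(months, "mean")$values[2, 2]))
  expect_true(is.na(climate_annual(months, "sum")$values[2, 2]))
  expect_error(climate_annual(months[1:11]), "12")
})

test_that("priority rasterisation keeps the maximum class per cell", {
  g <- toy_grid(4, 4)
  lines <- line_frame(
    geometry = list(
      cbind(c(0.05, 0.95), c(0.6, 0.6)),   # class 10, horizontal
      cbind(c(0.6, 0.6), c(0.05, 0.95)),   # class 14, vertical
      cbind(c(0.05, 0.95), c(0.12, 0.12))  # class 7: below retention
    ),
    priority = c(10, 14, 7)
  )
  r <- priority_rasterize(lines, g)
  expect_equal(r$values[2, 3], 14)          # crossing cell takes the max
  expect_equal(r$values[2, 1], 10)
  expect_equal(r$values[3, 3], 14)
  expect_equal(r$values[4, c(1, 2, 4)], rep(0, 3))   # class 7 dropped
  empty <- priority_rasterize(line_frame(list(), numeric()), g)
  expect_true(all(empty$values == 0))
})

test_that("rasterised line cells match a segment-rectangle oracle", {
  set.seed(33)
  g <- mastergrid(0.05, 0, 1, 20, 20)
  seg_hits_cell <- function(a, b, x0, x1, y0, y1) {
    # independent oracle: endpoint containment or crossing any cell edge
    inside <- function(p) p[1] >= x0 && p[1] <= x1 && p[2] >= y0 && p[2] <= y1
    if (inside(a) || inside(b)) return(TRUE)
    edges <- list(rbind(c(x0, y0), c(x1, y0)), rbind(c(x1, y0), c(x1, y1)),
                  rbind(c(x1, y1), c(x0, y1)), rbind(c(x0, y1), c(x0, y0)))
    ccw <- function(p, q, r) {
      (r[2] - p[2]) * (q[1] - p[1]) - (q[2] - p[2]) * (r[1] - p[1])
    }
    crosses <- function(p1, p2, p3, p4) {
      d1 <- ccw(p3, p4, p1); d2 <- ccw(p3, p4, p2)
      d3 <- ccw(p1, p2, p3); d4 <- ccw(p1, p2, p4)
      (d1 * d2 <= 0) && (d3 * d4 <= 0)
    }
    any(vapply(edges, function(e) crosses(a, b, e[1, ], e[2, ]), logical(1)))
  }
  for (k in 1:4) {
    seg <- matrix(runif(4), 2, 2)
    r <- priority_rasterize(line_frame(list(seg), 9), g)
    for (rr in seq_len(20)) for (cc in seq_len(20)) {
      x0 <- (cc - 1) * 0.05; y1 <- 1 - (rr - 1) * 0.05
      expect_equal(r$values[rr, cc] == 9,
                   seg_hits_cell(seg[1, ], seg[2, ], x0, x0 + 0.05,
                                 y1 - 0.05, y1))
    }
  }
})

test_that("offshore links are restored and on-land links discarded", {
  g <- toy_grid(2, 2)
  hw <- grid_raster(g, matrix(c(10, 0, 0, 0), 2, 2), "continuous")
  links <- grid_raster(g, matrix(c(1, 1, 0, 0), 2, 2), "binary")
  land <- grid_raster(g, matrix(c(1, 0, 1, 1), 2, 2), "binary")
  out <- restore_offshore_links(hw, links, land)
  expect_equal(out$values[2, 1], 30)             # offshore link written back
  expect_equal(out$values[1, 1], 10)             # on-land link discarded
  nolinks <- grid_raster(g, matrix(0, 2, 2), "binary")
  expect_identical(restore_offshore_links(hw, nolinks, land)$values, hw$values)
})

test_that("intersections require differing tags and at-grade crossings", {
  # same highway continuing through a shared endpoint: no intersection
  a <- cbind(c(0, 0.5), c(0.5, 0.5))
  b <- cbind(c(0.5, 1), c(0.5, 0.5))
  same <- line_frame(list(a, b), priority = 10, name = "M1")
  expect_equal(nrow(detect_intersections(same)), 0)

  # crossing ways with different names: one point at the crossing
  cross <- line_frame(list(cbind(c(0, 1), c(0, 1)), cbind(c(0, 1), c(1, 0))),
                      priority = c(10, 12), name = c("A", "B"))
  pts <- detect_intersections(cross)
  expect_equal(nrow(pts), 1)
  expect_equal(c(pts$lon, pts$lat), c(0.5, 0.5))

  # a bridge crossing is suppressed entirely
  bridged <- cross; bridged$link[2] <- TRUE
  expect_equal(nrow(detect_intersections(bridged)), 0)

  # symmetric in input order and invariant to vertex densification
  rev_pts <- detect_intersections(cross[2:1, ])
  expect_equal(rev_pts, pts)
  dense <- line_frame(
    list(cbind(c(0, 0.25, 0.5, 0.75, 1), c(0, 0.25, 0.5, 0.75, 1)),
         cbind(c(0, 1), c(1, 0))),
    priority = c(10, 12), name = c("A", "B"))
  expect_equal(detect_intersections(dense), pts)

  # ways outside the class range are ignored
  minor <- line_frame(list(cbind(c(0, 1), c(0, 1)), cbind(c(0, 1), c(1, 0))),
                      priority = c(5, 12), name = c("A", "B"))
  expect_equal(nrow(detect_intersections(minor)), 0)
})

test_that("the waterway union mosaics three binary sources", {
  g <- toy_grid(2, 2)
  wb <- grid_raster(g, matrix(c(1, 0, 0, 0), 2, 2), "binary")
  rb <- grid_raster(g, matrix(c(0, 1, 0, 0), 2, 2), "binary")
  ww <- grid_raster(g, matrix(c(0, 0, 1, 0), 2, 2), "binary")
  u <- waterway_union(wb, rb, ww)
  expect_equal(as.vector(u$values), c(1, 1, 1, 0))
})
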
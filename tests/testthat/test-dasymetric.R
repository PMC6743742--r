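# small shared fixture: 6x6 grid, two units split down the middle
dasy_fixture <- function() {
  g <- toy_grid(6, 6, cell = 1 / 6)
  admin <- grid_raster(g, cbind(matrix(1, 6, 3), matrix(2, 6, 3)),
                       "categorical")
  areas <- pixel_area_grid(g)
  list(g = g, admin = admin, areas = areas)
}

test_that("zonal summaries report means, proportions and areas", {
  fx <- dasy_fixture()
  cont <- grid_raster(fx$g, matrix(c(rep(2, 18), rep(4, 18)), 6, 6),
                      "continuous")
  catg <- grid_raster(fx$g, matrix(rep(c(1, 1, 1, 2, 2, 2), 6), 6, 6,
                                   byrow = TRUE), "categorical")
  stack <- covariate_stack(x = cont, lc = catg)
  s <- zonal_covariate_summary(stack, fx$admin, fx$areas)
  expect_equal(s$unit_id, c(1, 2))
  expect_equal(s$x, c(2, 4))
  expect_equal(s$lc_p1, c(1, 0))
  expect_equal(s$lc_p2, c(0, 1))
  expect_equal(s$n_cells, c(18, 18))
  expect_equal(s$area_m2,
               c(sum(fx$areas$values[, 1:3]), sum(fx$areas$values[, 4:6])))

  # two-cell unit with values 2 and 4 averages to 3; nodata is excluded
  cont$values[1, 1] <- NA
  s2 <- zonal_covariate_summary(covariate_stack(x = cont), fx$admin, fx$areas)
  expect_equal(s2$x[1], 2)   # remaining cells still all 2
  half <- grid_raster(fx$g, matrix(c(2, 4), 6, 6), "continuous")
  s3 <- zonal_covariate_summary(covariate_stack(x = half), fx$admin, fx$areas)
  expect_equal(s3$x, c(3, 3))
})

# a deterministic 12-unit training fixture with a log-linear signal
training_fixture <- function(seed = 9) {
  set.seed(seed)
  n <- 12
  summaries <- tibble::tibble(
    unit_id = seq_len(n), n_cells = 10, area_m2 = 1e6,
    x = seq(0, 1, length.out = n), z = runif(n), incomplete = FALSE
  )
  counts <- tibble::tibble(unit_id = seq_len(n),
                           count = 1e6 * exp(-10 + 3 * summaries$x))
  list(summaries = summaries, counts = counts)
}

test_that("a constant response yields a constant model", {
  fx <- training_fixture()
  const <- dplyr::mutate(fx$counts, count = 5e-4 * 1e6)
  expect_warning(m <- fit_density_model(fx$summaries, const, seed = 1),
                 "constant")
  g <- toy_grid(2, 2)
  stack <- covariate_stack(x = grid_raster(g, matrix(runif(4), 2, 2),
                                           "continuous"),
                           z = grid_raster(g, matrix(runif(4), 2, 2),
                                           "continuous"))
  w <- predict_weight_surface(m, stack, grid_raster(g, 1, "binary"))
  expect_true(all(abs(w$values - 5e-4) < 1e-12))
})

test_that("predictions are invariant to training row order at fixed seed", {
  fx <- training_fixture()
  m1 <- fit_density_model(fx$summaries, fx$counts, seed = 11)
  shuffle <- sample(nrow(fx$summaries))
  m2 <- fit_density_model(fx$summaries[shuffle, ], fx$counts, seed = 11)
  newdata <- data.frame(x = c(0.1, 0.5, 0.9), z = c(0.2, 0.5, 0.7))
  p1 <- predict(m1$forest, data = newdata, num.threads = 1)$predictions
  p2 <- predict(m2$forest, data = newdata, num.threads = 1)$predictions
  expect_identical(p1, p2)
})

test_that("too few or degenerate units are rejected", {
  fx <- training_fixture()
  expect_error(fit_density_model(fx$summaries[1:5, ], fx$counts, seed = 1),
               "10 units")
  expect_error(fit_density_model(fx$summaries, fx$counts), "seed")
})

test_that("weight surfaces are positive on land and match a cell oracle", {
  fx <- training_fixture()
  m <- fit_density_model(fx$summaries, fx$counts, seed = 3)
  g <- mastergrid(0.25, 0, 0.75, 3, 1)
  stack <- covariate_stack(
    x = grid_raster(g, matrix(c(0.1, 0.5, 0.9), 3, 1), "continuous"),
    z = grid_raster(g, matrix(c(0.3, 0.3, 0.3), 3, 1), "continuous")
  )
  land <- grid_raster(g, 1, "binary")
  w <- predict_weight_surface(m, stack, land)
  expect_true(all(w$values > 0))
  # per-cell single-prediction oracle
  for (i in 1:3) {
    one <- predict(m$forest,
                   data = data.frame(x = stack$x$values[i, 1],
                                     z = stack$z$values[i, 1]),
                   num.threads = 1)$predictions
    expect_equal(w$values[i, 1], exp(one))
  }
  # constant covariates give constant weights
  cstack <- covariate_stack(x = grid_raster(g, 0.4, "continuous"),
                            z = grid_raster(g, 0.4, "continuous"))
  cw <- predict_weight_surface(m, cstack, land)
  expect_equal(length(unique(as.vector(cw$values))), 1L)
  # a missing covariate is named in the rejection
  expect_error(predict_weight_surface(m, covariate_stack(
    x = grid_raster(g, 0.4, "continuous")), land), "z")
})

test_that("redistribution shares counts proportionally and conserves", {
  g <- toy_grid(2, 2)
  admin <- grid_raster(g, matrix(1, 2, 2), "categorical")
  counts <- tibble::tibble(unit_id = 1, count = 100)
  uni <- redistribute_counts(grid_raster(g, 1, "continuous"), admin, counts)
  expect_true(all(uni$population$values == 25))

  w13 <- grid_raster(mastergrid(0.25, 0, 0.25, 1, 2),
                     matrix(c(1, 3), 1, 2), "continuous")
  admin2 <- grid_raster(w13$grid, matrix(1, 1, 2), "categorical")
  out <- redistribute_counts(w13, admin2, counts)
  expect_equal(as.vector(out$population$values), c(25, 75))

  # scale invariance: multiplying weights by k changes nothing
  k9 <- grid_raster(w13$grid, matrix(c(9, 27), 1, 2), "continuous")
  expect_equal(redistribute_counts(k9, admin2, counts)$population$values,
               out$population$values)

  expect_error(redistribute_counts(w13, admin2,
    tibble::tibble(unit_id = c(1, 7), count = c(1, 2))), "7")
})

test_that("per-unit sums are machine-exact for random weights", {
  set.seed(55)
  g <- toy_grid(10, 10, cell = 0.1)
  admin <- grid_raster(g, matrix(sample(1:7, 100, replace = TRUE), 10, 10),
                       "categorical")
  counts <- tibble::tibble(unit_id = 1:7, count = runif(7, 10, 1e5))
  w <- grid_raster(g, matrix(runif(100), 10, 10), "continuous")
  out <- redistribute_counts(w, admin, counts)
  for (i in 1:7) {
    cells <- admin$values == counts$unit_id[i]
    expect_identical(sum(out$population$values[cells]), counts$count[i])
  }
  expect_identical(out$audit$output_sum, out$audit$input_count)

  # a zero-weight unit falls back to a uniform split
  w$values[admin$values == 3] <- 0
  out0 <- redistribute_counts(w, admin, counts)
  cells3 <- admin$values == 3
  expect_true(all(out0$population$values[cells3] ==
                    counts$count[3] / sum(cells3)))
  expect_true(out0$audit$uniform_fallback[out0$audit$unit_id == 3])
})

test_that("the areal baseline reduces to constant density within units", {
  fx <- dasy_fixture()
  aw <- areal_weight_baseline(fx$admin, fx$areas)
  counts <- tibble::tibble(unit_id = c(1, 2), count = c(900, 1800))
  pop <- redistribute_counts(aw, fx$admin, counts)$population
  dens <- pop$values / fx$areas$values
  expect_equal(max(dens[, 1:3]) / min(dens[, 1:3]), 1, tolerance = 1e-9)
  # equatorward rows have larger cells and so receive more population
  expect_true(all(diff(pop$values[, 1]) > 0))
  # two-cell share equals the area ratio
  expect_equal(pop$values[1, 1] / pop$values[6, 1],
               fx$areas$values[1, 1] / fx$areas$values[6, 1])
})

test_that("identical seeds give bit-identical weight surfaces", {
  fx <- training_fixture()
  m1 <- fit_density_model(fx$summaries, fx$counts, seed = 101)
  m2 <- fit_density_model(fx$summaries, fx$counts, seed = 101)
  g <- toy_grid(3, 3)
  set.seed(6)
  stack <- covariate_stack(x = grid_raster(g, matrix(runif(9), 3, 3),
                                           "continuous"),
                           z = grid_raster(g, matrix(runif(9), 3, 3),
                                           "continuous"))
  land <- grid_raster(g, 1, "binary")
  expect_identical(predict_weight_surface(m1, stack, land)$values,
                   predict_weight_surface(m2, stack, land)$values)
})

test_that("tidy and glance expose importances and fit metadata", {
  fx <- training_fixture()
  m <- fit_density_model(fx$summaries, fx$counts, seed = 2)
  td <- tidy(m)
  expect_setequal(td$feature, c("x", "z"))
  expect_equal(td$feature[1], "x")   # the informative feature dominates
  gl <- glance(m)
  expect_equal(gl$n_units, 12)
  expect_equal(gl$num_trees, 500)
  expect_equal(gl$seed, 2)
})
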
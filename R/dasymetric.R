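#' Named stack of co-registered covariate rasters
#'
#' @param ... Named `grid_raster`s sharing one mastergrid.
#' @return A `covariate_stack` (named list).
#' @export
covariate_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "grid_raster")) {
    layers <- layers[[1]]
  }
  if (is.null(names(layers)) || any(names(layers) == "") ||
      anyDuplicated(names(layers))) {
    stop("covariate layers must have unique names", call. = FALSE)
  }
  g <- layers[[1]]$grid
  for (l in layers) check_same_grid(g, l$grid, "covariate layers")
  structure(layers, class = "covariate_stack")
}

# feature schema: continuous -> one column; categorical/binary -> one
# indicator column per observed class
stack_schema <- function(stack) {
  purrr::imap(unclass(stack), function(l, nm) {
    if (l$kind == "continuous") {
      list(type = "continuous", classes = NULL)
    } else {
      list(type = "categorical",
           classes = sort(unique(l$values[!is.na(l$values)])))
    }
  })
}

#' Zonal covariate summaries per administrative unit
#'
#' One row per unit with at least one cell: the mean of each continuous
#' covariate, the class proportions of each categorical covariate
#' (columns `<name>_p<class>`), the unit's land area and its cell count.
#' No-data cells are excluded from means and proportions; a unit whose cells
#' are all no-data for some covariate is flagged `incomplete`.
#'
#' @param stack A [covariate_stack()].
#' @param admin Admin-ID `grid_raster`.
#' @param areas Continuous `grid_raster` of cell areas (m^2), e.g. from
#'   [pixel_area_grid()].
#' @return Tibble of unit summaries.
#' @export
zonal_covariate_summary <- function(stack, admin, areas) {
  g <- admin$grid
  check_same_grid(g, areas$grid)
  for (l in stack) check_same_grid(g, l$grid)
  ids <- admin_unit_ids(admin)
  zone <- as.vector(admin$values)
  cellarea <- as.vector(areas$values)
  schema <- stack_schema(stack)
  out <- tibble::tibble(
    unit_id = ids,
    n_cells = vapply(ids, function(u) sum(zone == u, na.rm = TRUE), numeric(1)),
    area_m2 = vapply(ids, function(u) {
      sum(cellarea[!is.na(zone) & zone == u], na.rm = TRUE)
    }, numeric(1))
  )
  incomplete <- rep(FALSE, length(ids))
  for (nm in names(stack)) {
    v <- as.vector(stack[[nm]]$values)
    if (schema[[nm]]$type == "continuous") {
      m <- vapply(ids, function(u) {
        vv <- v[!is.na(zone) & zone == u]
        if (all(is.na(vv))) NA_real_ else mean(vv, na.rm = TRUE)
      }, numeric(1))
      incomplete <- incomplete | is.na(m)
      out[[nm]] <- m
    } else {
      for (cl in schema[[nm]]$classes) {
        p <- vapply(ids, function(u) {
          vv <- v[!is.na(zone) & zone == u]
          vv <- vv[!is.na(vv)]
          if (!length(vv)) NA_real_ else mean(vv == cl)
        }, numeric(1))
        incomplete <- incomplete | is.na(p)
        out[[paste0(nm, "_p", cl)]] <- p
      }
    }
  }
  out$incomplete <- incomplete
  out
}

#' Fit the random-forest population-density model
#'
#' Regresses log population density (persons/m^2, floored at 1e-12 for
#' zero-count units) on the zonal covariate summaries with a random forest
#' (500 trees by default), mirroring the established RF dasymetric scheme.
#' Training rows are sorted by unit ID before fitting so predictions do not
#' depend on input row order; the forest is seeded and single-threaded for
#' bit-reproducibility. A response with zero variance short-circuits to a
#' constant model (with a warning) - a forest has nothing to learn there.
#'
#' @param summaries Tibble from [zonal_covariate_summary()].
#' @param counts Tibble `unit_id`, `count` (persons per unit).
#' @param seed Integer seed (mandatory).
#' @param num_trees Number of trees (default 500).
#' @param mtry Features tried per split (default: ranger's regression
#'   default, one third of the features).
#' @param density_floor Lower bound applied to density before the log
#'   transform (default 1e-12 persons/m^2).
#' @return A `density_model`.
#' @export
fit_density_model <- function(summaries, counts, seed, num_trees = 500,
                              mtry = NULL, density_floor = 1e-12) {
  if (missing(seed)) stop("a seed is mandatory for model fitting", call. = FALSE)
  df <- dplyr::inner_join(summaries, tibble::as_tibble(counts), by = "unit_id") |>
    dplyr::arrange(.data$unit_id)
  df <- dplyr::filter(df, !.data$incomplete, .data$area_m2 > 0)
  df$density <- df$count / df$area_m2
  if (sum(df$density > 0) < 10) {
    stop("need at least 10 units with positive density to fit", call. = FALSE)
  }
  feat_cols <- setdiff(names(df), c("unit_id", "n_cells", "area_m2",
                                    "incomplete", "count", "density"))
  y <- log(pmax(df$density, density_floor))
  x <- as.data.frame(df[feat_cols])
  if (stats::var(y) == 0) {
    warning("constant density across units: returning a constant model",
            call. = FALSE)
    model <- structure(list(constant = y[1], features = feat_cols,
                            seed = seed, training = df,
                            density_floor = density_floor),
                       class = "density_model")
    return(model)
  }
  rf <- ranger::ranger(
    x = x, y = y,
    num.trees = num_trees,
    mtry = mtry,
    importance = "impurity",
    seed = seed,
    num.threads = 1
  )
  structure(list(forest = rf, features = feat_cols, seed = seed,
                 training = df, density_floor = density_floor),
            class = "density_model")
}

#' @export
print.density_model <- function(x, ...) {
  if (!is.null(x$constant)) {
    cat(sprintf("<density_model> constant log-density %.6g (%d units)\n",
                x$constant, nrow(x$training)))
  } else {
    cat(sprintf(
      "<density_model> %d trees, %d features, %d units, OOB R^2 %.3f\n",
      x$forest$num.trees, length(x$features), nrow(x$training),
      x$forest$r.squared))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a density model: one row per feature with its importance
#'
#' @param x A `density_model`.
#' @param ... Unused.
#' @return Tibble `feature`, `importance` (impurity; zero for a constant
#'   model), sorted by decreasing importance.
#' @method tidy density_model
#' @export
tidy.density_model <- function(x, ...) {
  imp <- if (is.null(x$forest)) {
    stats::setNames(rep(0, length(x$features)), x$features)
  } else {
    ranger::importance(x$forest)
  }
  tibble::tibble(feature = names(imp), importance = as.numeric(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' One-row model summary
#'
#' @param x A `density_model`.
#' @param ... Unused.
#' @return Tibble with `n_units`, `n_features`, `num_trees`, `r_squared`
#'   (out-of-bag), `seed`.
#' @method glance density_model
#' @export
glance.density_model <- function(x, ...) {
  tibble::tibble(
    n_units = nrow(x$training),
    n_features = length(x$features),
    num_trees = if (is.null(x$forest)) 0L else x$forest$num.trees,
    r_squared = if (is.null(x$forest)) NA_real_ else x$forest$r.squared,
    seed = x$seed
  )
}

# per-cell feature matrix for land cells, in training-column order;
# NA covariate values are imputed with the training feature mean
cell_feature_frame <- function(model, stack, cells) {
  schema <- stack_schema(stack)
  cols <- list()
  for (nm in names(stack)) {
    v <- as.vector(stack[[nm]]$values)[cells]
    if (schema[[nm]]$type == "continuous") {
      cols[[nm]] <- v
    } else {
      for (cl in schema[[nm]]$classes) {
        cols[[paste0(nm, "_p", cl)]] <- as.numeric(!is.na(v) & v == cl)
      }
    }
  }
  missing <- setdiff(model$features, names(cols))
  if (length(missing)) {
    stop("covariate stack is missing model feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(cols, check.names = FALSE)[model$features]
  for (j in seq_along(df)) {
    nas <- is.na(df[[j]])
    if (any(nas)) df[[j]][nas] <- mean(model$training[[model$features[j]]],
                                       na.rm = TRUE)
  }
  df
}

#' Predict the per-pixel weighting surface
#'
#' Applies the fitted density model to each land cell's covariate vector
#' (categorical covariates become class indicators) and exponentiates the
#' predicted log density, giving a strictly positive weight on land and
#' no-data off land.
#'
#' @param model A `density_model` from [fit_density_model()].
#' @param stack A [covariate_stack()] carrying every training feature.
#' @param land Binary land mask `grid_raster`.
#' @return A `grid_raster` weight surface.
#' @export
predict_weight_surface <- function(model, stack, land) {
  g <- land$grid
  for (l in stack) check_same_grid(g, l$grid)
  cells <- which(!is.na(land$values) & land$values == 1)
  vals <- matrix(NA_real_, g$n_rows, g$n_cols)
  if (length(cells)) {
    df <- cell_feature_frame(model, stack, cells)
    pred <- if (!is.null(model$constant)) {
      rep(model$constant, nrow(df))
    } else {
      stats::predict(model$forest, data = df, num.threads = 1)$predictions
    }
    vals[cells] <- exp(pred)
  }
  grid_raster(g, vals, "continuous")
}

#' Dasymetrically redistribute unit counts over a weight surface
#'
#' Each unit's count is shared over its cells in proportion to the weight
#' surface: `pop(cell) = count(u) * w(cell) / sum(w over cells of u)`. Units
#' whose weights sum to zero fall back to a uniform split over their cells
#' (population must go somewhere). A final correction assigns the
#' floating-point residual to the unit's largest cell so per-unit sums equal
#' the input counts machine-exactly.
#'
#' @param w Weight-surface `grid_raster` (non-negative).
#' @param admin Admin-ID `grid_raster`; every unit in `counts` must appear
#'   (merge sub-pixel units first).
#' @param counts Tibble `unit_id`, `count`.
#' @return List with `population` (a `grid_raster` of persons per cell) and
#'   `audit` (tibble `unit_id`, `input_count`, `output_sum`, `n_cells`,
#'   `uniform_fallback`, `correction_applied`).
#' @export
redistribute_counts <- function(w, admin, counts) {
  check_same_grid(w$grid, admin$grid)
  counts <- tibble::as_tibble(counts)
  present <- admin_unit_ids(admin)
  absent <- setdiff(counts$unit_id, present)
  if (length(absent)) {
    stop("unit(s) absent from the admin raster (merge sub-pixel units first): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  g <- admin$grid
  pop <- matrix(NA_real_, g$n_rows, g$n_cols)
  audit <- vector("list", nrow(counts))
  for (i in seq_len(nrow(counts))) {
    u <- counts$unit_id[i]
    count <- counts$count[i]
    cells <- which(!is.na(admin$values) & admin$values == u)
    wu <- w$values[cells]
    wu[is.na(wu) | wu < 0] <- 0
    sw <- sum(wu)
    uniform <- sw == 0
    share <- if (uniform) rep(1 / length(cells), length(cells)) else wu / sw
    p <- count * share
    # residual correction for machine-exact per-unit conservation: the
    # residual is typically sub-ulp of the largest cells, so try absorbing it
    # into the smallest cells first and keep the first adjustment that makes
    # the recomputed sum close exactly
    correction <- 0
    for (k in 1:32) {
      res <- count - sum(p)
      if (res == 0) break
      placed <- FALSE
      for (j in order(p)) {
        q <- p
        q[j] <- q[j] + res
        if (sum(q) == count) {
          p <- q
          correction <- correction + res
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        # reachable sums move in 2-ulp steps here; a half-residual nudge
        # breaks the parity before retrying
        jm <- which.min(p)
        p[jm] <- p[jm] + res / 2
        correction <- correction + res / 2
      }
    }
    pop[cells] <- p
    audit[[i]] <- tibble::tibble(
      unit_id = u, input_count = count, output_sum = sum(p),
      n_cells = length(cells), uniform_fallback = uniform,
      correction_applied = correction
    )
  }
  list(population = grid_raster(g, pop, "continuous"),
       audit = dplyr::bind_rows(audit))
}

#' Areal-weighting baseline surface
#'
#' The classical baseline in which a cell's population is a function of its
#' land area alone: the weight is the cell area, so redistribution spreads a
#' unit's count uniformly per unit area (constant density within the unit).
#'
#' @param admin Admin-ID `grid_raster`.
#' @param areas Cell-area `grid_raster` (m^2).
#' @return Weight-surface `grid_raster` (area on unit cells, no-data off).
#' @export
areal_weight_baseline <- function(admin, areas) {
  check_same_grid(admin$grid, areas$grid)
  vals <- areas$values
  wc <- attr(admin, "water_code")
  off <- is.na(admin$values)
  if (!is.null(wc)) off <- off | admin$values == wc
  vals[off] <- NA_real_
  grid_raster(admin$grid, vals, "continuous")
}
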
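#' Polygon and line frames
#'
#' Vector features are carried as plain tibbles with a `geometry` list-column
#' of two-column matrices (lon, lat). Polygon frames have columns
#' `id` (positive, unique) and `geometry` (one outer ring per feature, open or
#' closed); line frames carry per-way attribute columns (`priority`, `name`,
#' `ref`, `junction`, `link`).
#'
#' @param id Positive unique feature IDs.
#' @param geometry List of two-column lon/lat matrices.
#' @return A tibble with class `polygon_frame` stacked on top.
#' @export
polygon_frame <- function(id = numeric(), geometry = list()) {
  stopifnot(length(id) == length(geometry))
  if (length(id) && (any(id <= 0) || anyDuplicated(id))) {
    stop("polygon IDs must be positive and unique", call. = FALSE)
  }
  geometry <- lapply(geometry, function(m) {
    m <- as.matrix(m)
    stopifnot(ncol(m) == 2, nrow(m) >= 3)
    # drop an explicit closing vertex; ring closure is implicit
    if (all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    unname(m)
  })
  out <- tibble::tibble(id = as.numeric(id), geometry = geometry)
  class(out) <- c("polygon_frame", class(out))
  out
}

# Ray-casting point-in-polygon on an open ring; boundary points count as
# inside on the low side (half-open convention, deterministic).
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  j <- n
  inside <- logical(length(px))
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Shoelace area of an open ring, in squared degrees (sign dropped).
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

#' Representative interior point of a polygon
#'
#' The midpoint of the widest horizontal chord at the latitude halfway up the
#' polygon's bounding box: guaranteed interior even for concave rings, unlike
#' the centroid.
#'
#' @param ring Two-column lon/lat matrix (open ring).
#' @return Numeric `c(lon, lat)`.
#' @export
representative_point <- function(ring) {
  ring <- as.matrix(ring)
  if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
  y0 <- (min(ring[, 2]) + max(ring[, 2])) / 2
  n <- nrow(ring)
  xs <- numeric(0)
  j <- n
  for (i in seq_len(n)) {
    yi <- ring[i, 2]; yj <- ring[j, 2]
    if ((yi > y0) != (yj > y0)) {
      xi <- ring[i, 1]; xj <- ring[j, 1]
      xs <- c(xs, xi + (y0 - yi) * (xj - xi) / (yj - yi))
    }
    j <- i
  }
  if (length(xs) < 2) {         # degenerate sliver: fall back to vertex mean
    return(c(mean(ring[, 1]), mean(ring[, 2])))
  }
  xs <- sort(xs)
  spans <- xs[seq(2, length(xs), by = 2)] - xs[seq(1, length(xs) - 1, by = 2)]
  k <- which.max(spans)
  c((xs[2 * k - 1] + xs[2 * k]) / 2, y0)
}

# Proper/touching intersection of segments p1-p2 and p3-p4.
# Returns NULL or the intersection point(s) as a matrix (collinear overlaps
# return shared endpoints only).
segment_intersection <- function(p1, p2, p3, p4, tol = 1e-12) {
  d1 <- p2 - p1; d2 <- p4 - p3
  denom <- d1[1] * d2[2] - d1[2] * d2[1]
  dp <- p3 - p1
  if (abs(denom) > tol) {
    t <- (dp[1] * d2[2] - dp[2] * d2[1]) / denom
    u <- (dp[1] * d1[2] - dp[2] * d1[1]) / denom
    if (t >= -tol && t <= 1 + tol && u >= -tol && u <= 1 + tol) {
      return(matrix(p1 + t * d1, ncol = 2))
    }
    return(NULL)
  }
  # parallel: report shared endpoints of collinear touching segments
  cross <- dp[1] * d1[2] - dp[2] * d1[1]
  if (abs(cross) > tol) return(NULL)
  pts <- NULL
  for (a in list(p1, p2)) for (b in list(p3, p4)) {
    if (max(abs(a - b)) < tol) pts <- rbind(pts, a)
  }
  pts
}

# Does segment a-b intersect the closed axis-aligned rectangle
# [x0,x1] x [y0,y1]? (Liang-Barsky clipping test.)
segment_hits_rect <- function(ax, ay, bx, by, x0, x1, y0, y1) {
  dx <- bx - ax; dy <- by - ay
  t0 <- 0; t1 <- 1
  for (k in 1:4) {
    p <- switch(k, -dx, dx, -dy, dy)
    q <- switch(k, ax - x0, x1 - ax, ay - y0, y1 - ay)
    if (p == 0) {
      if (q < 0) return(FALSE)
    } else {
      r <- q / p
      if (p < 0) { if (r > t1) return(FALSE); if (r > t0) t0 <- r }
      else       { if (r < t0) return(FALSE); if (r < t1) t1 <- r }
    }
  }
  TRUE
}

# All (row, col) cells of `grid` whose closed square a polyline touches.
cells_hit_by_line <- function(coords, grid) {
  s <- grid$cell_size
  ext <- grid_extent(grid)
  hits <- matrix(integer(0), 0, 2)
  for (i in seq_len(nrow(coords) - 1)) {
    ax <- coords[i, 1]; ay <- coords[i, 2]
    bx <- coords[i + 1, 1]; by <- coords[i + 1, 2]
    if (ax == bx && ay == by) next   # zero-length segments are ignored
    c0 <- max(1L, floor((min(ax, bx) - ext["west"]) / s) + 1L)
    c1 <- min(grid$n_cols, floor((max(ax, bx) - ext["west"]) / s) + 1L)
    r0 <- max(1L, floor((ext["north"] - max(ay, by)) / s) + 1L)
    r1 <- min(grid$n_rows, floor((ext["north"] - min(ay, by)) / s) + 1L)
    if (c1 < c0 || r1 < r0) next
    for (r in r0:r1) for (cc in c0:c1) {
      x0 <- ext["west"] + (cc - 1) * s; y1 <- ext["north"] - (r - 1) * s
      if (segment_hits_rect(ax, ay, bx, by, x0, x0 + s, y1 - s, y1)) {
        hits <- rbind(hits, c(r, cc))
      }
    }
  }
  unique(hits)
}
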
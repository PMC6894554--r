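# Planar polygon machinery. Two representations share the `hs_poly` class:
#   type "xy"   -- a single simple ring, vertices in counter-clockwise order
#   type "mask" -- a union of grid cells (used for isopleth territories)
# Coordinates are planar kilometres throughout; no geodesy.

#' Construct a vertex polygon
#'
#' @param xy Two-column matrix of vertices (km); the ring is closed
#'   implicitly and reordered counter-clockwise.
#' @return An `hs_poly` of type `"xy"`.
#' @export
polygon_xy <- function(xy) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2, nrow(xy) >= 3)
  if (ring_signed_area(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  structure(list(type = "xy", xy = unname(xy)), class = "hs_poly")
}

#' Construct a grid-mask polygon (union of cells)
#'
#' @param mask Logical matrix on `grid` (TRUE = inside).
#' @param grid An `hs_grid`.
#' @return An `hs_poly` of type `"mask"`.
#' @export
polygon_mask <- function(mask, grid) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)),
            nrow(mask) == grid$n_rows, ncol(mask) == grid$n_cols)
  structure(list(type = "mask", mask = mask > 0, grid = grid), class = "hs_poly")
}

#' @export
print.hs_poly <- function(x, ...) {
  cat(sprintf("<hs_poly type=%s area=%.2f km2>\n", x$type, poly_area(x)))
  invisible(x)
}

ring_signed_area <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1)
  sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]) / 2
}

#' Polygon area (km^2)
#' @param poly An `hs_poly`.
#' @export
poly_area <- function(poly) {
  if (poly$type == "xy") abs(ring_signed_area(poly$xy))
  else sum(poly$mask) * grid_cell_area(poly$grid)
}

#' Polygon centroid
#' @param poly An `hs_poly`.
#' @return Numeric `c(x, y)` (km).
#' @export
poly_centroid <- function(poly) {
  if (poly$type == "xy") {
    xy <- poly$xy; n <- nrow(xy); j <- c(2:n, 1)
    cr <- xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]
    a <- sum(cr) / 2
    if (abs(a) < 1e-12) return(colMeans(xy))
    c(sum((xy[, 1] + xy[j, 1]) * cr) / (6 * a),
      sum((xy[, 2] + xy[j, 2]) * cr) / (6 * a))
  } else {
    ctr <- grid_centers(poly$grid)
    idx <- which(poly$mask, arr.ind = TRUE)
    c(mean(ctr$x[idx[, 2]]), mean(ctr$y[idx[, 1]]))
  }
}

#' Test point containment
#' @param poly An `hs_poly`.
#' @param x,y Point coordinates (km).
#' @return Logical vector.
#' @export
poly_contains <- function(poly, x, y) {
  if (poly$type == "xy") {
    mgcv::in.out(rbind(poly$xy, poly$xy[1, ]), cbind(x, y))
  } else {
    idx <- grid_locate(poly$grid, x, y)
    out <- rep(FALSE, length(x))
    ok <- !is.na(idx$row)
    out[ok] <- poly$mask[cbind(idx$row[ok], idx$col[ok])]
    out
  }
}

#' Rasterize a polygon onto a grid
#' @param poly An `hs_poly`.
#' @param grid Target `hs_grid`.
#' @return Logical matrix (cell centre inside polygon).
#' @export
poly_rasterize <- function(poly, grid) {
  if (poly$type == "mask" && identical(poly$grid, grid)) return(poly$mask)
  ctr <- grid_centers(grid)
  out <- matrix(FALSE, grid$n_rows, grid$n_cols)
  bb <- poly_bbox(poly)
  cols <- which(ctr$x >= bb[1] - grid$cell_size & ctr$x <= bb[3] + grid$cell_size)
  rows <- which(ctr$y >= bb[2] - grid$cell_size & ctr$y <= bb[4] + grid$cell_size)
  if (!length(cols) || !length(rows)) return(out)
  pts <- expand.grid(x = ctr$x[cols], y = ctr$y[rows])
  inside <- poly_contains(poly, pts$x, pts$y)
  out[rows, cols] <- matrix(inside, nrow = length(cols))[, , drop = FALSE] |> t()
  out
}

#' Bounding box of a polygon
#' @param poly An `hs_poly`.
#' @return Numeric `c(x_min, y_min, x_max, y_max)`.
#' @export
poly_bbox <- function(poly) {
  if (poly$type == "xy") {
    c(min(poly$xy[, 1]), min(poly$xy[, 2]), max(poly$xy[, 1]), max(poly$xy[, 2]))
  } else {
    ctr <- grid_centers(poly$grid)
    idx <- which(poly$mask, arr.ind = TRUE)
    h <- poly$grid$cell_size / 2
    c(min(ctr$x[idx[, 2]]) - h, min(ctr$y[idx[, 1]]) - h,
      max(ctr$x[idx[, 2]]) + h, max(ctr$y[idx[, 1]]) + h)
  }
}

is_convex_ring <- function(xy, tol = 1e-9) {
  n <- nrow(xy)
  if (n < 3) return(FALSE)
  jm <- c(n, 1:(n - 1)); jp <- c(2:n, 1)
  cr <- (xy[, 1] - xy[jm, 1]) * (xy[jp, 2] - xy[, 2]) -
        (xy[, 2] - xy[jm, 2]) * (xy[jp, 1] - xy[, 1])
  all(cr >= -tol * max(abs(cr), 1))
}

# Sutherland-Hodgman: clip `subject` ring by CONVEX `clip` ring (both CCW)
clip_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    a <- clip[i, ]; b <- clip[if (i == nc) 1 else i + 1, ]
    if (nrow(out) == 0) return(out)
    inp <- out
    out <- matrix(numeric(0), 0, 2)
    n <- nrow(inp)
    side <- (b[1] - a[1]) * (inp[, 2] - a[2]) - (b[2] - a[2]) * (inp[, 1] - a[1])
    for (k in seq_len(n)) {
      kp <- if (k == n) 1 else k + 1
      cur_in <- side[k] >= -1e-12
      nxt_in <- side[kp] >= -1e-12
      if (cur_in) out <- rbind(out, inp[k, ])
      if (cur_in != nxt_in) {
        t <- side[k] / (side[k] - side[kp])
        out <- rbind(out, inp[k, ] + t * (inp[kp, ] - inp[k, ]))
      }
    }
  }
  out
}

#' Area of intersection of two polygons
#'
#' Exact Sutherland-Hodgman clipping when at least one polygon is a convex
#' ring; otherwise computed on a shared fine grid.
#'
#' @param a,b `hs_poly` objects.
#' @param cell Grid cell size (km) for the rasterized fallback.
#' @return Intersection area (km^2).
#' @export
poly_intersection_area <- function(a, b, cell = NULL) {
  if (a$type == "xy" && b$type == "xy") {
    ca <- is_convex_ring(a$xy); cb <- is_convex_ring(b$xy)
    if (ca || cb) {
      clipped <- if (cb) clip_convex(a$xy, b$xy) else clip_convex(b$xy, a$xy)
      if (nrow(clipped) < 3) return(0)
      return(abs(ring_signed_area(clipped)))
    }
  }
  if (a$type == "mask" && b$type == "mask" && identical(a$grid, b$grid))
    return(sum(a$mask & b$mask) * grid_cell_area(a$grid))
  bba <- poly_bbox(a); bbb <- poly_bbox(b)
  lo <- pmax(bba[1:2], bbb[1:2]); hi <- pmin(bba[3:4], bbb[3:4])
  if (any(hi <= lo)) return(0)
  if (is.null(cell)) cell <- max(max(hi - lo) / 400, 1e-6)
  g <- grid_spec(lo[1] - cell, lo[2] - cell,
                 lo[1] - cell + cell * ceiling((hi[1] - lo[1] + 2 * cell) / cell),
                 lo[2] - cell + cell * ceiling((hi[2] - lo[2] + 2 * cell) / cell), cell)
  sum(poly_rasterize(a, g) & poly_rasterize(b, g)) * cell^2
}

#' Jaccard overlap of two polygons on a grid
#' @param a,b `hs_poly` objects.
#' @param grid Shared `hs_grid` on which both are rasterized.
#' @return Intersection-over-union in [0, 1].
#' @export
poly_jaccard <- function(a, b, grid) {
  ma <- poly_rasterize(a, grid); mb <- poly_rasterize(b, grid)
  u <- sum(ma | mb)
  if (u == 0) return(0)
  sum(ma & mb) / u
}

#' Uniform random points inside a polygon
#' @param poly An `hs_poly`.
#' @param n Number of points.
#' @return `n x 2` matrix of coordinates. Uses the current RNG stream.
#' @export
sample_points_in_poly <- function(poly, n) {
  if (n <= 0) return(matrix(numeric(0), 0, 2))
  if (poly$type == "mask") {
    cells <- which(poly$mask, arr.ind = TRUE)
    pick <- cells[sample.int(nrow(cells), n, replace = TRUE), , drop = FALSE]
    ctr <- grid_centers(poly$grid); h <- poly$grid$cell_size / 2
    return(cbind(ctr$x[pick[, 2]] + stats::runif(n, -h, h),
                 ctr$y[pick[, 1]] + stats::runif(n, -h, h)))
  }
  bb <- poly_bbox(poly)
  out <- matrix(numeric(0), 0, 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    x <- stats::runif(m, bb[1], bb[3]); y <- stats::runif(m, bb[2], bb[4])
    keep <- poly_contains(poly, x, y)
    out <- rbind(out, cbind(x[keep], y[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

# random convex polygon of given area around a centre: jittered radii at
# sorted angles, convex hull, then exact area rescale about the centroid
random_convex_polygon <- function(center, area_km2, n_vert = 12, irregularity = 0.35) {
  ang <- sort(stats::runif(n_vert, 0, 2 * pi))
  rad <- sqrt(area_km2 / pi) * (1 + stats::runif(n_vert, -irregularity, irregularity))
  xy <- cbind(center[1] + rad * cos(ang), center[2] + rad * sin(ang))
  hull <- grDevices::chull(xy)
  p <- polygon_xy(xy[hull, , drop = FALSE])
  scale_polygon_to_area(p, area_km2)
}

# exact-area rescaling about the centroid (similarity transform)
scale_polygon_to_area <- function(poly, target_area) {
  stopifnot(poly$type == "xy")
  s <- sqrt(target_area / poly_area(poly))
  ctr <- poly_centroid(poly)
  polygon_xy(sweep(sweep(poly$xy, 2, ctr), 2, c(s, s), "*") + rep(ctr, each = nrow(poly$xy)))
}

# mitered offset of a convex CCW ring by signed distance d (outward positive);
# returns NULL when erosion collapses the ring
offset_convex <- function(xy, d) {
  n <- nrow(xy)
  jp <- c(2:n, 1)
  ex <- xy[jp, 1] - xy[, 1]; ey <- xy[jp, 2] - xy[, 2]
  len <- sqrt(ex^2 + ey^2)
  keep <- len > 1e-12
  xy <- xy[keep, , drop = FALSE]
  n <- nrow(xy)
  if (n < 3) return(NULL)
  jp <- c(2:n, 1)
  ex <- xy[jp, 1] - xy[, 1]; ey <- xy[jp, 2] - xy[, 2]
  len <- sqrt(ex^2 + ey^2)
  # outward normal of CCW edge is (ey, -ex)/len
  nx <- ey / len; ny <- -ex / len
  px <- xy[, 1] + d * nx; py <- xy[, 2] + d * ny
  out <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    h <- if (i == 1) n else i - 1   # previous edge index
    # intersect offset lines of edges h and i
    A <- rbind(c(nx[h], ny[h]), c(nx[i], ny[i]))
    b <- c(nx[h] * px[h] + ny[h] * py[h], nx[i] * px[i] + ny[i] * py[i])
    det <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
    if (abs(det) < 1e-12) { out[i, ] <- c(px[i], py[i]); next }
    out[i, ] <- solve(A, b)
  }
  if (ring_signed_area(out) <= 0 || !is_convex_ring(out, tol = 1e-6)) return(NULL)
  out
}
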
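# Territory estimation from telemetry and track locations: outlier
# screening, fixed-kernel utilization distributions, volume isopleths,
# minimum convex polygons, and the yearly / moving-window / long-term
# (A/B/C) method cascade.

#' Remove outlying relocations
#'
#' Screens locations before kernel estimation. A point is removed when its
#' distance from the coordinate-wise median centre exceeds the median of
#' those distances plus `k` times their MAD. With the default `k = 6` no
#' more than a few extreme fixes are dropped.
#'
#' @param locs LocationSet data.frame with `x_km`, `y_km`.
#' @param k MAD multiplier (> 0).
#' @return The subset of `locs` retained, original order preserved.
#' @export
remove_outliers <- function(locs, k = 6) {
  stopifnot(k > 0)
  if (nrow(locs) < 3) stop("too few points: need >= 3 locations")
  cx <- stats::median(locs$x_km); cy <- stats::median(locs$y_km)
  d <- sqrt((locs$x_km - cx)^2 + (locs$y_km - cy)^2)
  cut <- stats::median(d) + k * stats::mad(d)
  locs[d <= cut | abs(d - cut) < 1e-12, , drop = FALSE]
}

#' Fit a kernel utilization distribution
#'
#' Bivariate Gaussian-kernel density of relocations on a grid, with either a
#' two-stage plug-in bandwidth (one per coordinate; diagonal bandwidth
#' matrix) or the bivariate normal-reference rule h_j = sd_j * n^(-1/6).
#'
#' @param locs LocationSet data.frame with `x_km`, `y_km` (>= 30 rows, the
#'   usability threshold for territory estimation).
#' @param grid Optional `hs_grid`; by default a grid of `cell` km cells
#'   covering the points with a margin of 3 bandwidth sd.
#' @param bandwidth_method `"plug_in"` or `"normal_reference"`.
#' @param cell Default grid resolution (km).
#' @param min_locs Minimum usable number of locations.
#' @return A `utilization_dist`: list with `grid`, `mass` (cell probability
#'   masses summing to 1), `density` (per km^2) and `bandwidth` (2x2, km^2
#'   as variances).
#' @export
fit_kernel_ud <- function(locs, grid = NULL,
                          bandwidth_method = c("plug_in", "normal_reference"),
                          cell = 0.5, min_locs = 30) {
  bandwidth_method <- match.arg(bandwidth_method)
  n <- nrow(locs)
  if (n < min_locs) stop("too few points: need >= ", min_locs, " locations")
  x <- locs$x_km; y <- locs$y_km
  if (stats::sd(x) < 1e-9 || stats::sd(y) < 1e-9 ||
      abs(stats::cor(x, y)) > 1 - 1e-9)
    stop("degenerate bandwidth: location scatter is collinear or coincident")
  h <- if (bandwidth_method == "plug_in") {
    c(KernSmooth::dpik(x), KernSmooth::dpik(y))
  } else {
    c(stats::sd(x), stats::sd(y)) * n^(-1 / 6)
  }
  if (is.null(grid)) {
    m <- 3 * max(h)
    pad <- function(lo, hi) {
      lo <- lo - m; hi <- hi + m
      n_c <- ceiling((hi - lo) / cell)
      c(lo, lo + n_c * cell)
    }
    ex <- pad(min(x), max(x)); ey <- pad(min(y), max(y))
    grid <- grid_spec(ex[1], ey[1], ex[2], ey[2], cell)
  }
  ctr <- grid_centers(grid)
  # separable Gaussian kernel: D[r,c] = (1/n) sum_p phi_hx(xc_c - x_p) phi_hy(yc_r - y_p)
  Ky <- outer(ctr$y, y, function(g, p) stats::dnorm(g - p, sd = h[2]))
  Kx <- outer(ctr$x, x, function(g, p) stats::dnorm(g - p, sd = h[1]))
  dens <- (Ky %*% t(Kx)) / n
  mass <- dens * grid_cell_area(grid)
  mass <- mass / sum(mass)
  structure(list(grid = grid, mass = mass,
                 density = mass / grid_cell_area(grid),
                 bandwidth = diag(h^2), n = n,
                 bandwidth_method = bandwidth_method),
            class = "utilization_dist")
}

#' @export
print.utilization_dist <- function(x, ...) {
  cat(sprintf("<utilization_dist> n=%d, h=(%.3f, %.3f) km [%s], %d x %d grid\n",
              x$n, sqrt(x$bandwidth[1, 1]), sqrt(x$bandwidth[2, 2]),
              x$bandwidth_method, x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' Extract a volume isopleth from a utilization distribution
#'
#' The territory boundary: the smallest union of grid cells, taken in
#' decreasing density order, whose cumulative mass reaches `level`.
#'
#' @param ud A `utilization_dist`.
#' @param level Volume level in (0, 1); 0.95 defines the territory home range.
#' @return An `hs_poly` (grid-mask polygon).
#' @export
extract_isopleth <- function(ud, level = 0.95) {
  stopifnot(level > 0, level < 1)
  ord <- order(ud$mass, decreasing = TRUE)
  cum <- cumsum(ud$mass[ord])
  k <- which(cum >= level)[1]
  mask <- matrix(FALSE, ud$grid$n_rows, ud$grid$n_cols)
  mask[ord[seq_len(k)]] <- TRUE
  polygon_mask(mask, ud$grid)
}

#' Minimum convex polygon of locations
#'
#' @param locs LocationSet data.frame with `x_km`, `y_km` (>= 3
#'   non-collinear points).
#' @return An `hs_poly` (convex vertex polygon).
#' @export
minimum_convex_polygon <- function(locs) {
  if (nrow(locs) < 3) stop("degenerate polygon: need >= 3 points")
  pts <- cbind(locs$x_km, locs$y_km)
  hull <- grDevices::chull(pts)
  if (length(hull) < 3 || abs(ring_signed_area(pts[hull, , drop = FALSE])) < 1e-12)
    stop("degenerate polygon: points are collinear")
  polygon_xy(pts[hull, , drop = FALSE])
}

#' Estimate annual territories with the A/B/C method cascade
#'
#' For every pack-year the census matrix marks present, the cascade tries:
#' (i) a yearly kernel UD + isopleth when the year has at least `min_locs`
#' telemetry fixes ("A-yearly"); (ii) a 3-year moving-window UD when years
#' t-1..t+1 pool at least `min_locs` fixes ("A-window"); otherwise
#' (iii) method A (carry the pack's most recent estimated polygon forward),
#' then method B (kernel UD of all of the pack's telemetry plus track
#' locations pooled over the full series), then method C (minimum convex
#' polygon of all of the pack's track locations). Pack-years resolvable by
#' no method are listed in the `unresolved` attribute.
#'
#' @param all_locs Telemetry LocationSet (`pack_id`, `year`, `x_km`, `y_km`).
#' @param track_locs Track-survey LocationSet (same columns).
#' @param pack_years A `pack_year_matrix` (size >= 2 present, 0 absent, NA
#'   not-surveyed; run [fill_midpoint()] first if gaps remain).
#' @param min_locs Usability threshold (default 30 locations).
#' @param cell UD grid resolution (km).
#' @param level Isopleth volume level.
#' @param outlier_k MAD multiplier passed to [remove_outliers()].
#' @return List of `territory_record` objects with `method_tag` and
#'   `n_locations_used` set; attribute `unresolved` lists failures.
#' @export
estimate_territories <- function(all_locs, track_locs, pack_years,
                                 min_locs = 30, cell = 0.5, level = 0.95,
                                 outlier_k = 6) {
  yrs <- as.integer(colnames(pack_years))
  out <- list(); unresolved <- list()
  for (pid in rownames(pack_years)) {
    tel <- all_locs[all_locs$pack_id == pid, , drop = FALSE]
    trk <- track_locs[track_locs$pack_id == pid, , drop = FALSE]
    last_poly <- NULL; last_n <- NA_integer_
    pooled_poly <- NULL  # lazily computed method-B estimate
    for (j in seq_along(yrs)) {
      t <- yrs[j]
      sz <- pack_years[pid, j]
      if (is.na(sz) || sz < 2) next    # absent or unresolved not-surveyed
      rec <- NULL
      yearly <- tel[tel$year == t, , drop = FALSE]
      window <- tel[tel$year >= t - 1 & tel$year <= t + 1, , drop = FALSE]
      if (nrow(yearly) >= min_locs) {
        rec <- kde_record(yearly, pid, t, "A-yearly", cell, level, outlier_k, sz)
      } else if (nrow(window) >= min_locs) {
        rec <- kde_record(window, pid, t, "A-window", cell, level, outlier_k, sz)
      } else if (!is.null(last_poly)) {
        rec <- territory_record(pid, t, last_poly, size = sz, method_tag = "A",
                                n_locations_used = last_n)
      } else {
        pooled <- rbind(tel[, c("x_km", "y_km")], trk[, c("x_km", "y_km")])
        if (nrow(pooled) >= min_locs) {
          if (is.null(pooled_poly))
            pooled_poly <- kde_record(pooled, pid, t, "B", cell, level, outlier_k, sz)
          rec <- territory_record(pid, t, pooled_poly$polygon, size = sz,
                                  method_tag = "B",
                                  n_locations_used = pooled_poly$n_locations_used)
        } else if (nrow(trk) >= 3) {
          mcp <- try(minimum_convex_polygon(trk), silent = TRUE)
          if (!inherits(mcp, "try-error"))
            rec <- territory_record(pid, t, mcp, size = sz, method_tag = "C",
                                    n_locations_used = nrow(trk))
        }
      }
      if (is.null(rec)) {
        unresolved[[length(unresolved) + 1L]] <- list(pack_id = pid, year = t)
      } else {
        out[[length(out) + 1L]] <- rec
        # only kernel-based estimates are carried forward as method A;
        # track-only (C) packs keep their MCP and its tag every year
        if (rec$method_tag %in% c("A-yearly", "A-window", "A")) {
          last_poly <- rec$polygon; last_n <- rec$n_locations_used
        }
      }
    }
  }
  attr(out, "unresolved") <- unresolved
  out
}

kde_record <- function(locs, pid, t, tag, cell, level, outlier_k, sz) {
  locs <- remove_outliers(locs, k = outlier_k)
  ud <- fit_kernel_ud(locs, cell = cell)
  territory_record(pid, t, extract_isopleth(ud, level), size = sz,
                   method_tag = tag, n_locations_used = nrow(locs))
}
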
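# Monte-Carlo propagation of territory-boundary uncertainty into annual
# occupancy-probability rasters: resample each pack's territory area,
# rescale the baseline polygon to the sampled area, rasterize, and average
# binary occupancy over replicates.

#' Population-level territory area statistics
#'
#' Mean and sd of areas across all UD-based (methods A/B, or simulator
#' truth) territory records; the fallback distribution for packs without
#' telemetry-based estimates.
#'
#' @param records List of `territory_record`s (any years).
#' @return List `mean`, `sd`, `n`.
#' @export
territory_area_stats <- function(records) {
  ud_based <- vapply(records, function(r)
    !is.na(r$method_tag) && r$method_tag != "C", TRUE)
  a <- vapply(records[ud_based], function(r) r$area_km2, 0)
  if (!length(a)) a <- vapply(records, function(r) r$area_km2, 0)
  list(mean = mean(a), sd = if (length(a) > 1) stats::sd(a) else 0, n = length(a))
}

#' Sample a plausible territory area for one pack-year
#'
#' Packs with at least two telemetry-based (non-C) pack-years draw from a
#' pack-specific normal: mean = the current-year area for yearly/window/A
#' records, or the pack's long-term mean area for method B; sd = the
#' pack-specific sd of areas. Packs known only from tracks (method C) draw
#' from the population normal. Draws are truncated below at 10% of the mean.
#'
#' @param record The `territory_record` being perturbed.
#' @param pack_records All records of that pack across years.
#' @param population_stats Result of [territory_area_stats()].
#' @return A single area (km^2), using the current RNG stream.
#' @export
sample_territory_area <- function(record, pack_records, population_stats) {
  tel <- Filter(function(r) !is.na(r$method_tag) && r$method_tag != "C", pack_records)
  areas <- vapply(tel, function(r) r$area_km2, 0)
  if (!is.na(record$method_tag) && record$method_tag != "C" && length(areas) >= 2) {
    mu <- if (identical(record$method_tag, "B")) mean(areas) else record$area_km2
    sdv <- stats::sd(areas)
  } else {
    mu <- population_stats$mean
    sdv <- population_stats$sd
  }
  if (sdv <= 0) return(mu)
  max(stats::rnorm(1, mu, sdv), 0.1 * mu)
}

#' Rescale a polygon to a target area
#'
#' Convex vertex polygons are expanded or shrunk by a signed mitered edge
#' offset, with the offset distance found by bisection so the area matches
#' the target within `rel_tol` (for a square, doubling the side length is
#' an offset of half a side per edge). Grid-mask polygons and non-convex
#' rings are rescaled exactly by a similarity transform about the centroid.
#' If erosion would collapse the polygon, the minimal polygon at 10% of the
#' baseline area is returned with a warning.
#'
#' @param polygon An `hs_poly`.
#' @param target_area_km2 Target area (> 0).
#' @param rel_tol Relative area tolerance for the offset search.
#' @return A rescaled `hs_poly` (vertex type).
#' @export
rescale_polygon <- function(polygon, target_area_km2, rel_tol = 0.01) {
  stopifnot(target_area_km2 > 0)
  a0 <- poly_area(polygon)
  if (abs(target_area_km2 - a0) / target_area_km2 <= rel_tol) return(polygon)
  if (polygon$type == "mask") return(scale_mask_to_area(polygon, target_area_km2))
  if (!is_convex_ring(polygon$xy))
    return(scale_polygon_to_area(polygon, target_area_km2))
  if (target_area_km2 < 0.1 * a0) {
    warning("target area unreachable by erosion; returning minimal polygon at 10% of baseline")
    target_area_km2 <- 0.1 * a0
  }
  # bracket the signed offset: for a convex ring, dilation area grows as
  # A + P d + pi d^2, so this initial guess is close already
  per <- ring_perimeter(polygon$xy)
  d_hi <- max((target_area_km2 - a0) / per * 4, 1e-6)
  d_lo <- -max_inradius(polygon$xy)
  if (!is.finite(d_hi) || !is.finite(d_lo))
    return(scale_polygon_to_area(polygon, target_area_km2))
  f <- function(d) {
    xy <- offset_convex(polygon$xy, d)
    if (is.null(xy)) return(-target_area_km2)
    abs(ring_signed_area(xy)) - target_area_km2
  }
  tries <- 0L
  while (f(d_hi) < 0 && tries < 60L) { d_hi <- d_hi * 2; tries <- tries + 1L }
  root <- try(stats::uniroot(f, c(d_lo * 0.999, d_hi), tol = 1e-6), silent = TRUE)
  if (inherits(root, "try-error"))
    return(scale_polygon_to_area(polygon, target_area_km2))
  xy <- offset_convex(polygon$xy, root$root)
  if (is.null(xy)) {
    warning("erosion collapsed polygon; returning minimal polygon at 10% of baseline")
    return(scale_polygon_to_area(polygon, 0.1 * a0))
  }
  out <- polygon_xy(xy)
  if (abs(poly_area(out) - target_area_km2) / target_area_km2 > rel_tol)
    out <- scale_polygon_to_area(out, target_area_km2)
  out
}

ring_perimeter <- function(xy) {
  n <- nrow(xy); jp <- c(2:n, 1)
  sum(sqrt((xy[jp, 1] - xy[, 1])^2 + (xy[jp, 2] - xy[, 2])^2))
}

# largest inscribed-circle radius bound: min distance from centroid to edges
max_inradius <- function(xy) {
  ctr <- polygon_xy(xy) |> poly_centroid()
  n <- nrow(xy); jp <- c(2:n, 1)
  ex <- xy[jp, 1] - xy[, 1]; ey <- xy[jp, 2] - xy[, 2]
  len <- sqrt(ex^2 + ey^2)
  keep <- len > 1e-9                       # skip degenerate edges
  d <- abs(ex * (ctr[2] - xy[, 2]) - ey * (ctr[1] - xy[, 1]))[keep] / len[keep]
  if (!length(d) || !all(is.finite(d))) return(1e-6)
  max(min(d), 1e-6)
}

# exact similarity rescale of a mask territory: a cell is inside the scaled
# region iff its centre, inverse-scaled about the centroid, was inside
scale_mask_to_area <- function(polygon, target_area) {
  g <- polygon$grid
  s <- sqrt(target_area / poly_area(polygon))
  ctr <- poly_centroid(polygon)
  cc <- grid_centers(g)
  pts <- expand.grid(x = cc$x, y = cc$y)
  px <- ctr[1] + (pts$x - ctr[1]) / s
  py <- ctr[2] + (pts$y - ctr[2]) / s
  idx <- grid_locate(g, px, py)
  inside <- rep(FALSE, nrow(pts))
  ok <- !is.na(idx$row)
  inside[ok] <- polygon$mask[cbind(idx$row[ok], idx$col[ok])]
  mask <- matrix(FALSE, g$n_rows, g$n_cols)
  # expand.grid varies x (columns) fastest
  mask[cbind(rep(seq_len(g$n_rows), each = g$n_cols),
             rep(seq_len(g$n_cols), times = g$n_rows))] <- inside
  polygon_mask(mask, g)
}

#' Annual occupancy-probability raster from boundary uncertainty
#'
#' For each of `n_sim` replicates, every pack's territory area is resampled
#' ([sample_territory_area()]), the polygon rescaled to it, all rescaled
#' territories rasterized and unioned to a binary occupancy layer; the
#' output is the mean over replicates, i.e. the probability that each cell
#' falls within some pack territory that year. Each pack draws its areas
#' from its own seeded substream, so adding a pack leaves the other packs'
#' draws unchanged.
#'
#' @param year_records List of `territory_record`s for one year.
#' @param grid Target `hs_grid`.
#' @param n_sim Number of replicates (default 100).
#' @param all_records Records across all years (for pack-specific area sd);
#'   defaults to `year_records`.
#' @param seed Integer seed.
#' @return An `hs_raster` with values in [0, 1] (multiples of 1/n_sim) and
#'   attribute field `n_sim`.
#' @export
occupancy_probability <- function(year_records, grid, n_sim = 100,
                                  all_records = year_records, seed = 1L) {
  stopifnot(n_sim >= 1)
  acc <- matrix(0, grid$n_rows, grid$n_cols)
  if (length(year_records)) {
    pop <- territory_area_stats(all_records)
    # per-pack seeded substreams: one pack's draws never perturb another's
    draws <- lapply(year_records, function(rec) {
      set.seed(seed + pack_seed_offset(rec$pack_id))
      pack_recs <- Filter(function(r) identical(r$pack_id, rec$pack_id), all_records)
      vapply(seq_len(n_sim), function(s)
        sample_territory_area(rec, pack_recs, pop), 0)
    })
    for (s in seq_len(n_sim)) {
      u <- matrix(FALSE, grid$n_rows, grid$n_cols)
      for (i in seq_along(year_records)) {
        p <- rescale_polygon(year_records[[i]]$polygon, draws[[i]][s])
        u <- u | poly_rasterize(p, grid)
      }
      acc <- acc + u
    }
    acc <- acc / n_sim
  }
  out <- raster_new(grid, acc, year = if (length(year_records)) year_records[[1]]$year else NULL,
                    name = "occupancy_probability")
  out$n_sim <- n_sim
  out
}

pack_seed_offset <- function(pack_id) {
  sum(utf8ToInt(as.character(pack_id)) * seq_along(utf8ToInt(as.character(pack_id)))) %% 100000L
}
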
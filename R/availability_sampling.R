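# Per-pack-year used and unoccupied sampling domains, and the used/unused
# point draws that define the RSPF design table. The unused domain for a
# pack-year is a disc of radius equal to the 95% dispersal quantile
# (~165 km) about the territory centroid, minus the pack's own territory,
# with other occupied ground admissible only through an overlap allowance
# and down-weighted by 1 - P(occupied).

#' Total territory overlap proportion for one year
#'
#' Sum of all pairwise territory intersection areas divided by the sum of
#' territory areas; 0 for disjoint territories.
#'
#' @param year_records List of `territory_record`s for one year.
#' @param cell Fallback rasterization cell (km) for non-convex geometry.
#' @return Proportion in [0, 1).
#' @export
overlap_proportion <- function(year_records, cell = NULL) {
  n <- length(year_records)
  if (n == 0) stop("need >= 1 territory")
  if (n == 1) return(0)
  tot <- sum(vapply(year_records, function(r) r$area_km2, 0))
  inter <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    bi <- poly_bbox(year_records[[i]]$polygon)
    bj <- poly_bbox(year_records[[j]]$polygon)
    if (bi[1] > bj[3] || bj[1] > bi[3] || bi[2] > bj[4] || bj[2] > bi[4]) next
    inter <- inter + poly_intersection_area(year_records[[i]]$polygon,
                                            year_records[[j]]$polygon, cell = cell)
  }
  inter / tot
}

#' Build the available (unoccupied) sampling domain for a pack-year
#'
#' @param record The pack-year's `territory_record`.
#' @param occupancy The year's occupancy-probability `hs_raster`.
#' @param kernel A `dispersal_kernel`; the disc radius is its `q95`.
#' @param overlap_allowance Fraction of unused points allowed inside other
#'   occupied territories (default: supply the year's measured
#'   [overlap_proportion()]).
#' @param occupied_threshold P(occupied) above which a cell counts as other
#'   occupied ground.
#' @return An `availability_domain`: cells of the occupancy grid within the
#'   disc, split into own-territory, other-occupied and unoccupied, with
#'   inclusion weights 1 - P(occupied).
#' @export
build_available_domain <- function(record, occupancy, kernel = dispersal_kernel(),
                                   overlap_allowance = 0,
                                   occupied_threshold = 0.5) {
  stopifnot(overlap_allowance >= 0, overlap_allowance < 1)
  g <- occupancy$grid
  ctr <- poly_centroid(record$polygon)
  if (ctr[1] < g$x_min || ctr[1] > g$x_max || ctr[2] < g$y_min || ctr[2] > g$y_max)
    stop("invalid record: territory centroid outside the study area")
  cc <- grid_centers(g)
  dx <- outer(rep(1, g$n_rows), (cc$x - ctr[1])^2)
  dy <- outer((cc$y - ctr[2])^2, rep(1, g$n_cols))
  in_disc <- (dx + dy) <= kernel$q95^2
  own <- poly_rasterize(record$polygon, g)
  weight <- pmin(pmax(1 - occupancy$values, 0), 1)
  occ_other <- occupancy$values >= occupied_threshold & !own
  domain_cells <- in_disc & !own
  has_unocc <- any(domain_cells & !occ_other & weight > 0)
  has_occ_admissible <- overlap_allowance > 0 && any(domain_cells & occ_other)
  if (!has_unocc && !has_occ_admissible)
    warning("empty unused domain: all available ground is occupied with no overlap allowance")
  structure(list(pack_id = record$pack_id, year = record$year,
                 center = ctr, radius_km = kernel$q95, grid = g,
                 in_disc = in_disc, own = own, weight = weight,
                 occ_other = occ_other,
                 overlap_allowance = overlap_allowance),
            class = "availability_domain")
}

#' @export
print.availability_domain <- function(x, ...) {
  cat(sprintf("<availability_domain> pack %s year %s, radius %.1f km, allowance %.2f\n",
              x$pack_id, x$year, x$radius_km, x$overlap_allowance))
  invisible(x)
}

#' Draw used points inside a territory
#'
#' One point per `rate_km2` of territory (floor, minimum one): an average
#' 283 km^2 territory yields five used locations at the default rate of one
#' per 50 km^2.
#'
#' @param record A `territory_record`.
#' @param rate_km2 Area per used point.
#' @return Data.frame `x_km`, `y_km`, `pack_id`, `year`; uses the current
#'   RNG stream.
#' @export
draw_used <- function(record, rate_km2 = 50) {
  stopifnot(record$area_km2 > 0)
  n <- max(1L, floor(record$area_km2 / rate_km2))
  pts <- sample_points_in_poly(record$polygon, n)
  data.frame(x_km = pts[, 1], y_km = pts[, 2],
             pack_id = record$pack_id, year = record$year)
}

#' Draw unused points from an availability domain
#'
#' One point per `rate_km2` of the domain's geometric area (disc minus own
#' territory, clipped to the grid; floor, minimum one). A fraction equal to
#' the overlap allowance is drawn uniformly from other occupied territory
#' within the disc; the remainder is a spatially balanced weighted sample
#' of unoccupied ground with inclusion weight proportional to
#' 1 - P(occupied), realized as systematic sampling along a boustrophedon
#' (serpentine) ordering of the domain cells.
#'
#' @param domain An `availability_domain`.
#' @param rate_km2 Area per unused point.
#' @return Data.frame `x_km`, `y_km`, `pack_id`, `year`, `in_occupied`;
#'   uses the current RNG stream.
#' @export
draw_unused <- function(domain, rate_km2 = 1000) {
  g <- domain$grid
  cell_a <- grid_cell_area(g)
  eff_area <- sum(domain$in_disc & !domain$own) * cell_a
  if (eff_area <= 0) stop("no points: empty availability domain")
  n <- max(1L, floor(eff_area / rate_km2))
  n_occ <- round(domain$overlap_allowance * n)
  occ_cells <- which(domain$in_disc & domain$occ_other)
  if (!length(occ_cells)) n_occ <- 0L
  unocc <- domain$in_disc & !domain$own & !domain$occ_other
  w <- domain$weight * unocc
  if (sum(w) <= 0 && n - n_occ > 0) {
    if (!length(occ_cells)) stop("no points: empty availability domain")
    n_occ <- n  # degenerate: everything occupied, fall back to allowance cells
  }
  pts <- matrix(numeric(0), 0, 2); flag <- logical(0)
  if (n_occ > 0) {
    pick <- occ_cells[sample.int(length(occ_cells), n_occ, replace = TRUE)]
    pts <- rbind(pts, cell_jitter(g, pick))
    flag <- c(flag, rep(TRUE, n_occ))
  }
  n_bal <- n - n_occ
  if (n_bal > 0) {
    pick <- systematic_weighted_cells(g, w, n_bal)
    pts <- rbind(pts, cell_jitter(g, pick))
    flag <- c(flag, rep(FALSE, n_bal))
  }
  data.frame(x_km = pts[, 1], y_km = pts[, 2],
             pack_id = domain$pack_id, year = domain$year, in_occupied = flag)
}

# random point inside each listed cell
cell_jitter <- function(g, cells) {
  rc <- arrayInd(cells, c(g$n_rows, g$n_cols))
  cc <- grid_centers(g); h <- g$cell_size / 2
  cbind(cc$x[rc[, 2]] + stats::runif(length(cells), -h, h),
        cc$y[rc[, 1]] + stats::runif(length(cells), -h, h))
}

# spatially balanced weighted cell sample: serpentine ordering of the grid
# gives a 1-D tour in which nearby cells are spatially close; systematic
# sampling of the cumulative weights along the tour spreads the sample in
# space with inclusion probability proportional to weight
systematic_weighted_cells <- function(g, w, n) {
  ordmat <- matrix(seq_len(g$n_rows * g$n_cols), g$n_rows, g$n_cols)
  for (cjj in seq(2, g$n_cols, by = 2)) {
    if (cjj > g$n_cols) break
    ordmat[, cjj] <- rev(ordmat[, cjj])
  }
  tour <- as.vector(ordmat)
  wt <- as.vector(w)[tour]
  keep <- wt > 0
  tour <- tour[keep]; wt <- wt[keep]
  cw <- cumsum(wt)
  total <- cw[length(cw)]
  u <- (stats::runif(1) + 0:(n - 1)) / n * total
  tour[findInterval(u, cw, left.open = TRUE) + 1L]
}

#' Assemble the RSPF design table
#'
#' Joins used (y = 1) and unused (y = 0) points with covariate values,
#' regional wolf density, pack id and year. Covariates and density are
#' sampled at the nearest cell and standardized with shared scalers so all
#' rows are on one scale; points falling off the rasters are dropped and
#' logged in the `dropped` attribute.
#'
#' @param used Data.frame from [draw_used()] rows (any number of pack-years).
#' @param unused Data.frame from [draw_unused()] rows.
#' @param stack A `covariate_stack` (unstandardized, original units).
#' @param density_raster An `hs_raster` of regional wolf density, or a named
#'   list of them by year.
#' @param scalers Optional `scaler_record` covering the layers and
#'   `wolf_density`; computed from the assembled table when missing.
#' @return A `SampleTable` data.frame: `y`, `x_km`, `y_km`, `pack_id`,
#'   `year`, one standardized column per layer, `wolf_density`
#'   (standardized), with the `scaler_record` in attribute `scalers`.
#' @export
assemble_sample_table <- function(used, unused, stack, density_raster,
                                  scalers = NULL) {
  used$y <- 1L
  if (!("in_occupied" %in% names(used))) used$in_occupied <- NA
  unused$y <- 0L
  if (!("in_occupied" %in% names(unused))) unused$in_occupied <- NA
  tab <- rbind(used[, c("y", "x_km", "y_km", "pack_id", "year", "in_occupied")],
               unused[, c("y", "x_km", "y_km", "pack_id", "year", "in_occupied")])
  for (nm in names(stack$layers))
    tab[[nm]] <- raster_extract(raster_new(stack$grid, stack$layers[[nm]]),
                                tab$x_km, tab$y_km)
  dens_of <- function(yr, x, y) {
    r <- if (inherits(density_raster, "hs_raster")) density_raster
         else density_raster[[as.character(yr)]]
    raster_extract(r, x, y)
  }
  tab$wolf_density <- NA_real_
  for (yr in unique(tab$year)) {
    ii <- which(tab$year == yr)
    tab$wolf_density[ii] <- dens_of(yr, tab$x_km[ii], tab$y_km[ii])
  }
  covs <- c(names(stack$layers), "wolf_density")
  keep <- stats::complete.cases(tab[, covs])
  dropped <- tab[!keep, c("pack_id", "year", "x_km", "y_km")]
  tab <- tab[keep, , drop = FALSE]
  if (is.null(scalers)) {
    sc <- standardize(lapply(covs, function(nm) tab[[nm]]) |> stats::setNames(covs))
    scalers <- sc$scalers
  }
  for (nm in covs) tab[[nm]] <- scale_apply(scalers, tab[[nm]], nm)
  tab$pack_id <- factor(tab$pack_id)
  tab$year <- factor(tab$year)
  rownames(tab) <- NULL
  attr(tab, "scalers") <- scalers
  attr(tab, "dropped") <- dropped
  tab
}
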
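# Plain-text interchange: location CSVs, pack-year matrices, GeoJSON
# territory collections. Rasters travel as ESRI ASCII grids (see grid.R).

#' Read / write location tables
#'
#' @param locs Data.frame with `pack_id`, `year`, `x_km`, `y_km`.
#' @param path CSV path.
#' @export
write_locations <- function(locs, path) {
  utils::write.csv(locs[, c("pack_id", "year", "x_km", "y_km")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_locations
#' @export
read_locations <- function(path) {
  utils::read.csv(path, colClasses = c(pack_id = "character"))
}

#' Read / write a pack-year matrix
#'
#' Cells hold the observed size (>= 2), 0 for absent and NA for
#' not-surveyed.
#'
#' @param m A `pack_year_matrix`.
#' @param path CSV path.
#' @export
write_pack_year_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_pack_year_matrix
#' @export
read_pack_year_matrix <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  structure(as.matrix(d), class = c("pack_year_matrix", "matrix"))
}

#' Write territory records as GeoJSON
#'
#' One Feature per record with a closed polygon ring and `pack_id`, `year`,
#' `area_km2`, `method_tag` and `n_locations` properties. Mask territories
#' are written as the convex hull of their cell centres (an approximation
#' noted in the feature properties).
#'
#' @param records List of `territory_record`s.
#' @param path Output path.
#' @export
write_territories_geojson <- function(records, path) {
  feats <- lapply(records, function(r) {
    ring <- territory_ring(r$polygon)
    list(type = "Feature",
         properties = list(pack_id = r$pack_id, year = r$year,
                           area_km2 = r$area_km2, method_tag = r$method_tag,
                           n_locations = r$n_locations_used,
                           geometry_source = if (r$polygon$type == "mask")
                             "convex hull of mask cells" else "vertex ring"),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)), function(i)
                           c(ring[i, 1], ring[i, 2])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

#' @rdname write_territories_geojson
#' @export
read_territories_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  lapply(obj$features, function(f) {
    xy <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    xy <- xy[-nrow(xy), , drop = FALSE]   # drop closing vertex
    p <- f$properties
    territory_record(p$pack_id, p$year, polygon_xy(xy),
                     method_tag = p$method_tag,
                     n_locations_used = if (is.null(p$n_locations)) NA_integer_
                                        else p$n_locations)
  })
}

territory_ring <- function(poly) {
  xy <- if (poly$type == "xy") poly$xy else {
    ctr <- grid_centers(poly$grid)
    idx <- which(poly$mask, arr.ind = TRUE)
    pts <- cbind(ctr$x[idx[, 2]], ctr$y[idx[, 1]])
    pts[grDevices::chull(pts), , drop = FALSE]
  }
  rbind(xy, xy[1, ])
}

#' Per-pack-year estimation log
#'
#' @param records List of `territory_record`s.
#' @param path Optional CSV path; when given, the log is also written.
#' @return Data.frame `pack_id`, `year`, `method_tag`, `n_locations`,
#'   `area_km2`.
#' @export
territory_log <- function(records, path = NULL) {
  d <- do.call(rbind, lapply(records, function(r)
    data.frame(pack_id = r$pack_id, year = r$year, method_tag = r$method_tag,
               n_locations = r$n_locations_used, area_km2 = r$area_km2)))
  if (!is.null(path)) utils::write.csv(d, path, row.names = FALSE)
  d
}
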
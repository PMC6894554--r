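# Covariate engineering shared by real and synthetic inputs: circular focal
# means, exponential distance decay, and standardization with a stored
# scaler so model output can be mapped back to original units.

#' Circular focal mean of a raster layer
#'
#' Each cell becomes the mean of cells whose centres fall within a circular
#' assessment window; edge cells use the truncated window. The default
#' window area of 50.75 km^2 (radius ~4.019 km) is one quarter of a mean
#' wolf home range, chosen to pick up within-territory variability while
#' still representing landscape-level pattern.
#'
#' @param raster An `hs_raster` (or plain matrix plus `grid`).
#' @param window_area_km2 Window area; radius = sqrt(area / pi).
#' @param grid Required if `raster` is a plain matrix.
#' @return Smoothed `hs_raster`.
#' @export
focal_mean <- function(raster, window_area_km2 = 50.75, grid = NULL) {
  if (is.matrix(raster)) raster <- raster_new(grid, raster)
  radius <- sqrt(window_area_km2 / pi)
  cells <- radius / raster$grid$cell_size
  if (cells < 1) {
    warning("focal window smaller than one cell; returning input unchanged")
    return(raster)
  }
  raster_new(raster$grid, focal_mean_mat(raster$values, cells),
             year = raster$year, name = raster$name)
}

#' Exponential distance decay
#'
#' Converts distances to a proximity index exp(-d / alpha). When `alpha_km`
#' is not given it is estimated as the mean distance over a supplied set of
#' used locations, so the index equals exp(-1) at a typical used distance.
#'
#' @param d Distances (km): vector, matrix or `hs_raster`.
#' @param alpha_km Decay scale (> 0 km).
#' @param used_distances Distances at used locations, from which `alpha_km`
#'   is estimated when missing.
#' @return Same shape as `d`, values in (0, 1].
#' @export
distance_decay <- function(d, alpha_km = NULL, used_distances = NULL) {
  if (is.null(alpha_km)) {
    if (is.null(used_distances) || !length(used_distances))
      stop("invalid parameter: supply alpha_km or used_distances")
    alpha_km <- mean(used_distances)
  }
  if (any(!is.finite(alpha_km)) || any(alpha_km <= 0))
    stop("invalid parameter: alpha_km must be > 0")
  if (inherits(d, "hs_raster"))
    return(raster_new(d$grid, exp(-d$values / alpha_km), year = d$year, name = d$name))
  exp(-d / alpha_km)
}

#' Standardize covariate layers and record the scaler
#'
#' Centres and scales each layer to mean 0, sd 1 over the basis (population
#' sd, i.e. divisor n). The returned `scaler_record` allows exact round
#' trips between standardized and original units, and is reused to
#' standardize sample-table columns so points and rasters share one scale.
#'
#' @param stack A `covariate_stack` (or named list of matrices).
#' @param basis Optional data.frame whose columns (matching layer names)
#'   define the standardization basis; defaults to the full layers.
#' @return List with `stack` (standardized) and `scalers` (a
#'   `scaler_record` data.frame: `name`, `mean`, `sd`). Constant layers are
#'   dropped with a warning and listed in the `dropped` attribute.
#' @export
standardize <- function(stack, basis = NULL) {
  layers <- if (inherits(stack, "covariate_stack")) stack$layers else stack
  scalers <- data.frame(name = character(0), mean = numeric(0), sd = numeric(0))
  out <- list(); dropped <- character(0)
  for (nm in names(layers)) {
    v <- if (!is.null(basis) && nm %in% names(basis)) basis[[nm]] else as.vector(layers[[nm]])
    mu <- mean(v)
    sdv <- sqrt(mean((v - mu)^2))   # population sd
    if (sdv <= 0) {
      warning("degenerate covariate '", nm, "' is constant; dropped")
      dropped <- c(dropped, nm)
      next
    }
    scalers <- rbind(scalers, data.frame(name = nm, mean = mu, sd = sdv))
    out[[nm]] <- (layers[[nm]] - mu) / sdv
  }
  res <- if (inherits(stack, "covariate_stack")) {
    s <- stack; s$layers <- out
    s$truth_weights <- s$truth_weights[names(s$truth_weights) %in% names(out)]
    s
  } else out
  attr(scalers, "sd_type") <- "population"
  class(scalers) <- c("scaler_record", "data.frame")
  structure(list(stack = res, scalers = scalers), dropped = dropped)
}

#' Apply or invert a stored scaler
#'
#' @param scalers A `scaler_record`.
#' @param x Numeric vector (or matrix) in original (`scale_apply`) or
#'   standardized (`scale_invert`) units.
#' @param name Covariate name to look up.
#' @return Transformed values.
#' @export
scale_apply <- function(scalers, x, name) {
  i <- match(name, scalers$name)
  if (is.na(i)) stop("unknown covariate '", name, "' in scaler record")
  (x - scalers$mean[i]) / scalers$sd[i]
}

#' @rdname scale_apply
#' @export
scale_invert <- function(scalers, x, name) {
  i <- match(name, scalers$name)
  if (is.na(i)) stop("unknown covariate '", name, "' in scaler record")
  x * scalers$sd[i] + scalers$mean[i]
}

#' Serialize a scaler record to JSON (and back)
#'
#' @param scalers A `scaler_record`.
#' @param path File path for the JSON sidecar.
#' @return `read_scalers` returns the `scaler_record`.
#' @export
write_scalers <- function(scalers, path) {
  jsonlite::write_json(list(sd_type = attr(scalers, "sd_type"),
                            scalers = as.data.frame(scalers)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scalers
#' @export
read_scalers <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- obj$scalers
  attr(sc, "sd_type") <- obj$sd_type
  class(sc) <- c("scaler_record", "data.frame")
  sc
}
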
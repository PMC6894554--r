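#' Define a planar raster grid
#'
#' All gridded quantities in the package (covariate layers, utilization
#' distributions, density and occupancy rasters) live on a regular planar
#' grid in kilometre coordinates. Rows index the y axis (row 1 is the
#' southernmost row), columns the x axis.
#'
#' @param x_min,y_min,x_max,y_max Grid extent (km).
#' @param cell_size Cell edge length (km).
#' @return An object of class `hs_grid` with fields `x_min`, `y_min`,
#'   `x_max`, `y_max`, `cell_size`, `n_rows`, `n_cols`.
#' @export
grid_spec <- function(x_min, y_min, x_max, y_max, cell_size) {
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("invalid configuration: cell_size must be > 0")
  if (x_max <= x_min || y_max <= y_min)
    stop("invalid configuration: empty extent")
  n_cols <- max(1L, as.integer(round((x_max - x_min) / cell_size)))
  n_rows <- max(1L, as.integer(round((y_max - y_min) / cell_size)))
  if (abs(n_cols * cell_size - (x_max - x_min)) > 1e-6 ||
      abs(n_rows * cell_size - (y_max - y_min)) > 1e-6)
    stop("invalid configuration: extent is not a whole number of cells")
  structure(list(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
                 cell_size = cell_size, n_rows = n_rows, n_cols = n_cols),
            class = "hs_grid")
}

#' @export
print.hs_grid <- function(x, ...) {
  cat(sprintf("<hs_grid> %d x %d cells of %g km, extent [%g, %g] x [%g, %g] km\n",
              x$n_rows, x$n_cols, x$cell_size, x$x_min, x$x_max, x$y_min, x$y_max))
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param grid An `hs_grid`.
#' @return List with `x` (length `n_cols`) and `y` (length `n_rows`) centres.
#' @export
grid_centers <- function(grid) {
  list(x = grid$x_min + (seq_len(grid$n_cols) - 0.5) * grid$cell_size,
       y = grid$y_min + (seq_len(grid$n_rows) - 0.5) * grid$cell_size)
}

#' @rdname grid_centers
#' @export
grid_cell_area <- function(grid) grid$cell_size^2

# row/col index of points; NA outside the grid
grid_locate <- function(grid, x, y) {
  col <- floor((x - grid$x_min) / grid$cell_size) + 1
  row <- floor((y - grid$y_min) / grid$cell_size) + 1
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Construct a raster (values on a grid)
#'
#' @param grid An `hs_grid`.
#' @param values Numeric matrix `n_rows x n_cols` (or a scalar, recycled).
#' @param year Optional year label.
#' @param name Optional layer name.
#' @return Object of class `hs_raster` with fields `grid`, `values`, `year`, `name`.
#' @export
raster_new <- function(grid, values, year = NULL, name = NULL) {
  if (length(values) == 1L) values <- matrix(values, grid$n_rows, grid$n_cols)
  stopifnot(nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  structure(list(grid = grid, values = values, year = year, name = name),
            class = "hs_raster")
}

#' @export
print.hs_raster <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("<hs_raster>%s %d x %d cells of %g km, values in [%.4g, %.4g]\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              x$grid$n_rows, x$grid$n_cols, x$grid$cell_size, rng[1], rng[2]))
  invisible(x)
}

#' Extract raster values at point locations (nearest cell)
#' @param raster An `hs_raster`.
#' @param x,y Point coordinates (km).
#' @return Numeric vector; NA for points off the grid.
#' @export
raster_extract <- function(raster, x, y) {
  idx <- grid_locate(raster$grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx$row)
  out[ok] <- raster$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Write / read a raster as ESRI ASCII grid (plain text)
#'
#' Plain-text raster interchange: one header block
#' (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value) followed by rows
#' from north to south.
#'
#' @param raster An `hs_raster`.
#' @param path File path.
#' @return `read_asc` returns an `hs_raster`; `write_asc` returns `path`
#'   invisibly.
#' @export
write_asc <- function(raster, path) {
  g <- raster$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", g$n_cols),
               sprintf("nrows %d", g$n_rows),
               sprintf("xllcorner %.10g", g$x_min),
               sprintf("yllcorner %.10g", g$y_min),
               sprintf("cellsize %.10g", g$cell_size),
               "NODATA_value -9999"), con)
  vals <- raster$values
  vals[is.na(vals)] <- -9999
  for (r in rev(seq_len(g$n_rows)))
    writeLines(paste(formatC(vals[r, ], format = "g", digits = 10), collapse = " "), con)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- do.call(rbind, lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  vals <- vals[rev(seq_len(nrow(vals))), , drop = FALSE]
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  g <- grid_spec(hdr$xllcorner, hdr$yllcorner,
                 hdr$xllcorner + hdr$ncols * hdr$cellsize,
                 hdr$yllcorner + hdr$nrows * hdr$cellsize, hdr$cellsize)
  raster_new(g, vals)
}
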
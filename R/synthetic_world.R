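# Synthetic study systems: autocorrelated landscapes, territorial
# recolonization under ideal pre-emptive settlement, VHF-style telemetry and
# winter track surveys. Everything downstream of the generator treats its
# output exactly like field data, so the whole pipeline can be validated
# against a known generative truth.

#' Generate a stack of spatially autocorrelated covariate layers
#'
#' Each layer is a stationary Gaussian-process-like field built by
#' circular-FFT smoothing of white noise with a Gaussian filter, then scaled
#' to the requested marginal variance (sill). `spatial_range` is the lag at
#' which spatial correlation decays to 0.05.
#'
#' @param grid An `hs_grid`.
#' @param layer_specs List of specs, each a list with `name`,
#'   `spatial_range` (km), `sill` (variance), optional `weight` (true
#'   suitability weight used only by the simulator; default 0) and optional
#'   `transform` (function applied to the field).
#' @param seed Integer seed; identical seeds reproduce the stack exactly.
#' @return A `covariate_stack`: list with `grid`, `layers` (named list of
#'   matrices) and `truth_weights` (named numeric).
#' @export
generate_landscape <- function(grid, layer_specs, seed = 1L) {
  stopifnot(inherits(grid, "hs_grid"))
  for (sp in layer_specs) {
    if (is.null(sp$spatial_range) || sp$spatial_range <= 0)
      stop("invalid configuration: spatial_range must be > 0")
    if (is.null(sp$sill) || sp$sill < 0)
      stop("invalid configuration: sill must be >= 0")
  }
  set.seed(seed)
  layers <- list(); w <- numeric(0)
  for (sp in layer_specs) {
    layers[[sp$name]] <- grf_layer(grid, sp$spatial_range, sp$sill)
    if (!is.null(sp$transform)) layers[[sp$name]] <- sp$transform(layers[[sp$name]])
    w[sp$name] <- if (is.null(sp$weight)) 0 else sp$weight
  }
  structure(list(grid = grid, layers = layers, truth_weights = w),
            class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("<covariate_stack> %d layers on %d x %d grid: %s\n",
              length(x$layers), x$grid$n_rows, x$grid$n_cols,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

grf_layer <- function(grid, spatial_range, sill) {
  nr <- grid$n_rows; nc <- grid$n_cols
  if (sill == 0) return(matrix(0, nr, nc))
  # Gaussian smoothing of white noise; field correlation exp(-d^2/(4 s^2))
  # equals 0.05 at d = spatial_range
  s_km <- spatial_range / (2 * sqrt(log(20)))
  s <- s_km / grid$cell_size
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  kr <- gauss_kernel_1d(s, nr); kc <- gauss_kernel_1d(s, nc)
  # circular (torus) convolution keeps the field stationary to the edge
  f <- Re(stats::fft(stats::fft(z) * outer(stats::fft(kr), stats::fft(kc)),
                     inverse = TRUE)) / (nr * nc)
  f <- f - mean(f)
  f * sqrt(sill) / stats::sd(as.vector(f))
}

gauss_kernel_1d <- function(s, n) {
  d <- pmin(0:(n - 1), n - (0:(n - 1)))  # circular distance
  k <- exp(-d^2 / (2 * s^2))
  k / sum(k)
}

#' True habitat suitability of a synthetic landscape
#'
#' The simulator's generative linear predictor: the weighted sum of layers
#' using the stack's truth weights. Used for settlement ordering, telemetry
#' placement and recovery checks; the estimation pipeline never sees it.
#'
#' @param stack A `covariate_stack`.
#' @return An `hs_raster`.
#' @export
true_suitability <- function(stack) {
  v <- matrix(0, stack$grid$n_rows, stack$grid$n_cols)
  for (nm in names(stack$layers)) {
    w <- stack$truth_weights[[nm]]
    if (!is.null(w) && w != 0) v <- v + w * stack$layers[[nm]]
  }
  raster_new(stack$grid, v, name = "true_suitability")
}

#' Simulate territorial recolonization of a landscape
#'
#' Total abundance follows logistic growth; abundance divided by the mean
#' pack size sets the number of packs each year. New packs settle
#' pre-emptively (IPD; the ideal despotic case uses the same
#' best-site-first mechanics here) at the highest-true-suitability centre
#' still admissible, where admissibility reflects the year's target
#' territory-overlap proportion: candidate centres are scored with a
#' circle-approximation of the total overlap they would induce, and the
#' top-suitability candidate whose induced overlap best tracks the schedule
#' is chosen. Territories are random convex polygons with areas drawn from
#' a truncated normal; a pack keeps its territory for life.
#'
#' @param stack A `covariate_stack` (its truth weights define suitability).
#' @param years Number of years to simulate.
#' @param growth List `N0` (initial wolves), `K` (carrying capacity, wolves),
#'   `r` (intrinsic growth rate per year).
#' @param territory_area_dist List `mean_km2`, `sd_km2`; areas truncated > 0.
#' @param settlement_rule `"IPD"` or `"IDD"` (shared implementation).
#' @param overlap_schedule Numeric vector (recycled to `years`) of target
#'   total overlap proportions in [0, 1).
#' @param mean_pack_size Mean wolves per pack (sizes are >= 2).
#' @param seed Integer seed.
#' @return A `world_history`: list with `years`, `packs` (one data-free list
#'   of territory records per year), `abundance`, `realized_overlap`,
#'   `dispersal_rate` and the inputs.
#' @export
simulate_recolonization <- function(stack, years = 19,
                                    growth = list(N0 = 10, K = 240, r = 0.35),
                                    territory_area_dist = list(mean_km2 = 283.10, sd_km2 = 171.41),
                                    settlement_rule = c("IPD", "IDD"),
                                    overlap_schedule = 0,
                                    mean_pack_size = 4,
                                    seed = 1L) {
  settlement_rule <- match.arg(settlement_rule)
  stopifnot(growth$N0 >= 2, growth$K > growth$N0, territory_area_dist$mean_km2 > 0)
  set.seed(seed)
  suit <- true_suitability(stack)$values
  grid <- stack$grid
  ctr <- grid_centers(grid)
  sched <- rep_len(overlap_schedule, years)
  if (any(sched < 0 | sched >= 1)) stop("invalid configuration: overlap_schedule must be in [0,1)")

  t_seq <- seq_len(years)
  N <- growth$K * growth$N0 * exp(growth$r * (t_seq - 1)) /
    (growth$K + growth$N0 * (exp(growth$r * (t_seq - 1)) - 1))
  n_packs_year <- pmax(1L, round(N / mean_pack_size))

  # suitability-ordered candidate centres (cells)
  ord <- order(suit, decreasing = TRUE)
  cand_rc <- arrayInd(ord, dim(suit))
  cand_xy <- cbind(ctr$x[cand_rc[, 2]], ctr$y[cand_rc[, 1]])
  cand_suit <- suit[ord]

  packs <- list()          # living packs: pack_id, center, polygon, area, size, settle_year
  history <- vector("list", years)
  realized <- numeric(years)
  next_id <- 1L
  prev_int <- 0            # running sum of pairwise intersection areas
  tot_prev_area <- 0       # running sum of territory areas

  draw_area <- function() {
    a <- -1
    while (a <= 0) a <- stats::rnorm(1, territory_area_dist$mean_km2, territory_area_dist$sd_km2)
    a
  }

  for (t in t_seq) {
    need <- n_packs_year[t] - length(packs)
    if (t == 1 && need > 0) {
      # capacity check: enough vacant landscape for the founding packs
      if (need * territory_area_dist$mean_km2 >
          0.95 * grid$n_rows * grid$n_cols * grid_cell_area(grid))
        stop("capacity error: landscape too small to place initial territories")
    }
    while (need > 0) {
      area <- draw_area()
      # draw the territory shape first, then search for its best centre
      shape <- random_convex_polygon(c(0, 0), area)
      pick <- pick_settlement(packs, cand_xy, shape, sched[t], grid,
                              prev_int, tot_prev_area)
      if (is.na(pick$idx)) {
        if (length(packs) == 0)
          stop("capacity error: landscape too small to place initial territories")
        break
      }
      center <- cand_xy[pick$idx, ]
      poly <- polygon_xy(sweep(shape$xy, 2, center, "+"))
      size <- 2L + stats::rpois(1, mean_pack_size - 2)
      packs[[length(packs) + 1L]] <- list(pack_id = sprintf("P%03d", next_id),
                                          center = center,
                                          max_radius = shape_max_radius(shape),
                                          polygon = poly, area_km2 = area,
                                          size = size, settle_year = t)
      prev_int <- prev_int + pick$new_int
      tot_prev_area <- tot_prev_area + area
      next_id <- next_id + 1L
      need <- need - 1L
    }
    # mild size fluctuation, floored at 2 (packs, not lone wolves)
    packs <- lapply(packs, function(p) {
      p$size <- max(2L, p$size + sample(c(-1L, 0L, 1L), 1, prob = c(0.25, 0.5, 0.25)))
      p
    })
    history[[t]] <- lapply(packs, function(p)
      territory_record(p$pack_id, t, p$polygon, size = p$size,
                       method_tag = "truth", center = p$center,
                       settle_year = p$settle_year))
    realized[t] <- overlap_proportion(history[[t]])
  }

  structure(list(years = t_seq, packs = history, abundance = N,
                 n_packs = vapply(history, length, 1L),
                 realized_overlap = realized, overlap_schedule = sched,
                 dispersal_rate = 1 / 55, settlement_rule = settlement_rule,
                 growth = growth, territory_area_dist = territory_area_dist,
                 grid = grid, seed = seed),
            class = "world_history")
}

#' @export
print.world_history <- function(x, ...) {
  cat(sprintf("<world_history> %d years, %d -> %d packs, overlap %.2f -> %.2f\n",
              length(x$years), x$n_packs[1], x$n_packs[length(x$n_packs)],
              x$realized_overlap[1], x$realized_overlap[length(x$years)]))
  invisible(x)
}

shape_max_radius <- function(shape) {
  ctr <- poly_centroid(shape)
  max(sqrt((shape$xy[, 1] - ctr[1])^2 + (shape$xy[, 2] - ctr[2])^2))
}

# choose a settlement centre for a pre-drawn territory shape: walk
# candidates in decreasing suitability, compute the exact polygon overlap
# the translated shape would induce against nearby territories, and take
# the best-suitability candidate whose induced total overlap best tracks
# the target (for target 0 this is the best fully vacant centre)
pick_settlement <- function(packs, cand_xy, shape, target, grid,
                            prev_int, tot_prev_area, n_consider = 40L) {
  area_new <- poly_area(shape)
  rad <- shape_max_radius(shape)
  margin <- rad * 0.5
  inside <- cand_xy[, 1] > grid$x_min + margin & cand_xy[, 1] < grid$x_max - margin &
            cand_xy[, 2] > grid$y_min + margin & cand_xy[, 2] < grid$y_max - margin
  if (!length(packs)) {
    i <- which(inside)[1]
    return(list(idx = if (is.na(i)) NA_integer_ else i, new_int = 0))
  }
  px <- vapply(packs, function(p) p$center[1], 0)
  py <- vapply(packs, function(p) p$center[2], 0)
  pr <- vapply(packs, function(p) p$max_radius, 0)
  tot_area <- tot_prev_area + area_new
  idx <- which(inside)
  best <- NA_integer_; best_new_int <- 0; best_score <- Inf; considered <- 0L
  for (i in idx) {
    d <- sqrt((px - cand_xy[i, 1])^2 + (py - cand_xy[i, 2])^2)
    if (any(d < 0.5 * pmin(rad, pr))) next   # never stack directly on a centre
    near <- which(d < rad + pr)
    new_int <- 0
    if (length(near)) {
      cand_poly <- polygon_xy(sweep(shape$xy, 2, cand_xy[i, ], "+"))
      new_int <- sum(vapply(near, function(k)
        poly_intersection_area(cand_poly, packs[[k]]$polygon), 0))
    }
    if (target == 0 && new_int > 1e-9) next   # disjoint worlds stay disjoint
    ov <- (prev_int + new_int) / tot_area
    score <- abs(ov - target)
    considered <- considered + 1L
    # prefer earlier (higher-suitability) candidates on near-ties
    if (score < best_score - 0.005) { best_score <- score; best <- i; best_new_int <- new_int }
    if (best_score <= 0.01 || considered >= n_consider) break
  }
  list(idx = best, new_int = best_new_int)
}

#' Construct a territory record
#'
#' @param pack_id Pack identifier.
#' @param year Year index.
#' @param polygon An `hs_poly`.
#' @param size Pack size (wolves), if known.
#' @param method_tag How the boundary was estimated (`"A-yearly"`,
#'   `"A-window"`, `"A"`, `"B"`, `"C"`, or `"truth"` for simulator output).
#' @param n_locations_used Locations behind the estimate.
#' @param center Optional settlement centre (simulator only).
#' @param settle_year Optional settlement year (simulator only).
#' @return A `territory_record`.
#' @export
territory_record <- function(pack_id, year, polygon, size = NA_integer_,
                             method_tag = NA_character_,
                             n_locations_used = NA_integer_,
                             center = NULL, settle_year = NULL) {
  structure(list(pack_id = pack_id, year = year, polygon = polygon,
                 area_km2 = poly_area(polygon), size = size,
                 method_tag = method_tag, n_locations_used = n_locations_used,
                 center = center, settle_year = settle_year),
            class = "territory_record")
}

#' Simulate aerial VHF telemetry relocations
#'
#' Collared packs yield `fixes_per_pack_year` fixes per year. Within a
#' territory, fixes follow a use distribution proportional to
#' exp(true suitability) (the generative habitat truth), contracted toward
#' the territory centroid so use concentrates in the interior; a small
#' Gaussian location error is added.
#'
#' @param history A `world_history`.
#' @param stack The `covariate_stack` the world was built on (for the true
#'   use weights); omit for uniform-within-territory fixes.
#' @param fixes_per_pack_year Fixes per collared pack per year (weekly
#'   monitoring default 52).
#' @param collared_fraction Fraction of packs carrying a collar.
#' @param error_sd_km Telemetry location error sd (km).
#' @param seed Integer seed.
#' @return A `LocationSet` data.frame: `pack_id`, `year`, `x_km`, `y_km`.
#' @export
simulate_telemetry <- function(history, stack = NULL, fixes_per_pack_year = 52,
                               collared_fraction = 0.7, error_sd_km = 0.2,
                               seed = 1L) {
  stopifnot(fixes_per_pack_year >= 0, collared_fraction >= 0, collared_fraction <= 1)
  set.seed(seed)
  ids <- unique(unlist(lapply(history$packs, function(yy)
    vapply(yy, function(r) r$pack_id, ""))))
  collared <- character(0)
  if (length(ids) && collared_fraction > 0)
    collared <- sample(ids, max(if (collared_fraction > 0) 1L else 0L,
                                round(collared_fraction * length(ids))))
  suit <- if (is.null(stack)) NULL else true_suitability(stack)
  rows <- list()
  for (t in history$years) {
    for (rec in history$packs[[t]]) {
      if (!(rec$pack_id %in% collared) || fixes_per_pack_year == 0) next
      pts <- sample_use_points(rec$polygon, fixes_per_pack_year, suit)
      pts <- pts + matrix(stats::rnorm(2 * nrow(pts), 0, error_sd_km), ncol = 2)
      rows[[length(rows) + 1L]] <- data.frame(pack_id = rec$pack_id, year = t,
                                              x_km = pts[, 1], y_km = pts[, 2])
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pack_id = character(0), year = integer(0),
               x_km = numeric(0), y_km = numeric(0))
  rownames(out) <- NULL
  out
}

# use-weighted, interior-concentrated points in a territory
sample_use_points <- function(poly, n, suit = NULL) {
  cen <- poly_centroid(poly)
  got <- matrix(numeric(0), 0, 2)
  while (nrow(got) < n) {
    m <- max(4L * (n - nrow(got)), 32L)
    p <- sample_points_in_poly(poly, m)
    # contraction toward the centroid concentrates use in the interior
    lam <- sqrt(stats::runif(m))            # radial density ~ uniform disc
    lam <- 0.25 + 0.75 * lam                # keep some boundary use
    p <- cbind(cen[1] + lam * (p[, 1] - cen[1]), cen[2] + lam * (p[, 2] - cen[2]))
    if (!is.null(suit)) {
      w <- exp(raster_extract(suit, p[, 1], p[, 2]))
      w[is.na(w)] <- 0
      keep <- stats::runif(m) < w / max(w)
      p <- p[keep, , drop = FALSE]
    }
    got <- rbind(got, p)
  }
  got[seq_len(n), , drop = FALSE]
}

#' Simulate a winter track survey
#'
#' Each pack-year is detected with probability `detection_prob`; detected
#' pack-years record the true pack size. Years in `panel_gap_years` are
#' recorded as not-surveyed (NA) for every pack, exercising downstream
#' midpoint extrapolation. Detected territories also yield track locations
#' (boundary vertices plus interior points; at least 3 per pack).
#'
#' @param history A `world_history`.
#' @param detection_prob Per pack-year detection probability in (0, 1].
#' @param panel_gap_years Integer years recorded as not-surveyed.
#' @param n_interior_tracks Interior track points per detected pack-year.
#' @param seed Integer seed.
#' @return List with `matrix` (a `pack_year_matrix`: rows = packs, cols =
#'   years; size >= 2 present, 0 absent, NA not-surveyed) and `tracks`
#'   (a LocationSet data.frame).
#' @export
simulate_track_survey <- function(history, detection_prob = 1,
                                  panel_gap_years = integer(0),
                                  n_interior_tracks = 5, seed = 1L) {
  stopifnot(detection_prob > 0, detection_prob <= 1)
  set.seed(seed)
  ids <- unique(unlist(lapply(history$packs, function(yy)
    vapply(yy, function(r) r$pack_id, ""))))
  yrs <- history$years
  m <- matrix(0, nrow = length(ids), ncol = length(yrs),
              dimnames = list(ids, as.character(yrs)))
  rows <- list()
  for (t in yrs) {
    if (t %in% panel_gap_years) { m[, as.character(t)] <- NA; next }
    for (rec in history$packs[[t]]) {
      if (stats::runif(1) > detection_prob) next   # missed: stays 0
      m[rec$pack_id, as.character(t)] <- rec$size
      verts <- if (rec$polygon$type == "xy") rec$polygon$xy else
        sample_points_in_poly(rec$polygon, 8)
      inter <- sample_points_in_poly(rec$polygon, max(3 - nrow(verts), n_interior_tracks))
      pts <- rbind(verts, inter)
      rows[[length(rows) + 1L]] <- data.frame(pack_id = rec$pack_id, year = t,
                                              x_km = pts[, 1], y_km = pts[, 2])
    }
  }
  tracks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pack_id = character(0), year = integer(0),
               x_km = numeric(0), y_km = numeric(0))
  rownames(tracks) <- NULL
  list(matrix = structure(m, class = c("pack_year_matrix", "matrix")),
       tracks = tracks)
}
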
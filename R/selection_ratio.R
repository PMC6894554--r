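# Theory simulations of used and available habitat distributions under
# increasing occupancy, and empirical used:available summaries. The
# selection ratio f_u(X) / f_a(X) is the use-to-availability density ratio
# for a habitat covariate: > 1 indicates selection, < 1 avoidance. Under
# strong territoriality the available distribution itself shifts as
# occupancy rises, so the ratio can steepen, flatten or switch sign
# depending on how the two distributions converge or diverge.

#' Configure a used/available occupancy scenario
#'
#' Scenarios are 1-D Gaussian families whose means and sds follow linear
#' paths in occupancy. The four named presets reproduce the qualitative
#' outcomes for an important limited habitat (available quality collapses
#' faster than used: selection ratio at high covariate values grows with
#' occupancy), an important abundant habitat (used converges to the stable
#' available distribution: ratio flattens toward 1), a limited
#' substitutable habitat and an abundant substitutable habitat.
#'
#' @param scenario One of `"limited_important"`, `"abundant_important"`,
#'   `"limited_substitutable"`, `"abundant_substitutable"`.
#' @param occupancy Strictly increasing occupancy levels in [0, 1].
#' @param used_path,available_path Lists `mean0`, `mean_slope`, `sd0`,
#'   `sd_slope`: distribution mean = mean0 + mean_slope * occupancy (sd
#'   likewise). Defaults depend on the scenario.
#' @return A `scenario_config`.
#' @export
scenario_config <- function(scenario = c("limited_important", "abundant_important",
                                         "limited_substitutable", "abundant_substitutable"),
                            occupancy = seq(0.1, 0.9, by = 0.2),
                            used_path = NULL, available_path = NULL) {
  scenario <- match.arg(scenario)
  if (any(diff(occupancy) <= 0) || any(occupancy < 0 | occupancy > 1))
    stop("occupancy levels must be strictly increasing in [0, 1]")
  defaults <- switch(scenario,
    limited_important = list(
      used = list(mean0 = 1.0, mean_slope = -0.5, sd0 = 1, sd_slope = 0),
      avail = list(mean0 = 0.0, mean_slope = -1.5, sd0 = 1, sd_slope = 0)),
    abundant_important = list(
      used = list(mean0 = 1.0, mean_slope = -1.0, sd0 = 1, sd_slope = 0),
      avail = list(mean0 = 0.0, mean_slope = 0.0, sd0 = 1, sd_slope = 0)),
    limited_substitutable = list(
      used = list(mean0 = 0.8, mean_slope = -1.2, sd0 = 1, sd_slope = 0.2),
      avail = list(mean0 = 0.0, mean_slope = -0.4, sd0 = 1, sd_slope = 0)),
    abundant_substitutable = list(
      used = list(mean0 = 0.5, mean_slope = 0.0, sd0 = 1, sd_slope = 0),
      avail = list(mean0 = 0.0, mean_slope = 0.0, sd0 = 1, sd_slope = 0)))
  structure(list(scenario = scenario, occupancy = occupancy,
                 used_path = if (is.null(used_path)) defaults$used else used_path,
                 available_path = if (is.null(available_path)) defaults$avail else available_path),
            class = "scenario_config")
}

path_params <- function(path, occ) {
  list(mean = path$mean0 + path$mean_slope * occ,
       sd = pmax(path$sd0 + path$sd_slope * occ, 1e-6))
}

#' Simulate a used/available scenario and its selection-ratio curves
#'
#' Draws used and available samples from the configured Gaussian families
#' at each occupancy level, estimates both densities on a shared grid with
#' a kernel smoother, and returns the pointwise ratio f_u / f_a (undefined
#' where f_a falls below `floor`).
#'
#' @param config A `scenario_config`.
#' @param n_draws Draws per distribution per level (>= 1000).
#' @param seed Integer seed.
#' @param n_grid Evaluation grid size.
#' @param floor Availability density floor below which the ratio is NA.
#' @return A `selection_ratio_sim` list: `x` (grid), per-level `f_u`, `f_a`
#'   (density matrices), `ratio` (matrix), `occupancy`, `config`.
#' @export
simulate_scenario <- function(config, n_draws = 10000, seed = 1L,
                              n_grid = 512, floor = 1e-8) {
  stopifnot(n_draws >= 1000)
  set.seed(seed)
  occ <- config$occupancy
  pu <- path_params(config$used_path, occ)
  pa <- path_params(config$available_path, occ)
  if (any(pu$sd <= 1e-6) || any(pa$sd <= 1e-6))
    stop("degenerate sd: point-mass distributions are not supported")
  lo <- min(pu$mean - 4 * pu$sd, pa$mean - 4 * pa$sd)
  hi <- max(pu$mean + 4 * pu$sd, pa$mean + 4 * pa$sd)
  x <- seq(lo, hi, length.out = n_grid)
  f_u <- f_a <- matrix(NA_real_, n_grid, length(occ),
                       dimnames = list(NULL, as.character(occ)))
  for (j in seq_along(occ)) {
    du <- stats::density(stats::rnorm(n_draws, pu$mean[j], pu$sd[j]),
                         from = lo, to = hi, n = n_grid)
    da <- stats::density(stats::rnorm(n_draws, pa$mean[j], pa$sd[j]),
                         from = lo, to = hi, n = n_grid)
    f_u[, j] <- du$y
    f_a[, j] <- da$y
  }
  ratio <- f_u / pmax(f_a, floor)
  ratio[f_a < floor] <- NA
  structure(list(x = x, f_u = f_u, f_a = f_a, ratio = ratio,
                 occupancy = occ, config = config, n_draws = n_draws),
            class = "selection_ratio_sim")
}

#' @export
print.selection_ratio_sim <- function(x, ...) {
  cat(sprintf("<selection_ratio_sim> '%s', %d occupancy levels, %d draws each\n",
              x$config$scenario, length(x$occupancy), x$n_draws))
  invisible(x)
}

#' Empirical used and available means and their ratio across years
#'
#' Per year: the mean of a covariate among used (y = 1) points, among
#' unused (y = 0) points, and the ratio of the two means, all in original
#' units when a scaler record is available; ordered by that year's mean
#' regional density.
#'
#' @param tables A SampleTable (with `year`) or list of per-year tables.
#' @param covariate Covariate column name.
#' @param density_by_year Named numeric: mean regional density per year (in
#'   any consistent units; used only for ordering and the x axis).
#' @param scalers Optional `scaler_record`; defaults to the table's.
#' @return Data.frame `year`, `density`, `used_mean`, `available_mean`,
#'   `ratio` (NA with a flag attribute when the available mean is 0),
#'   ordered by density.
#' @export
empirical_selection_ratio <- function(tables, covariate, density_by_year,
                                      scalers = NULL) {
  if (is.data.frame(tables)) {
    if (is.null(scalers)) scalers <- attr(tables, "scalers")
    tables <- split(tables, tables$year)
  }
  rows <- list(); flagged <- character(0)
  for (yr in names(tables)) {
    tb <- tables[[yr]]
    if (!all(c(0, 1) %in% tb$y)) stop("year ", yr, " lacks one of the classes")
    v <- tb[[covariate]]
    if (!is.null(scalers) && covariate %in% scalers$name)
      v <- scale_invert(scalers, v, covariate)
    um <- mean(v[tb$y == 1]); am <- mean(v[tb$y == 0])
    ratio <- if (abs(am) < 1e-12) { flagged <- c(flagged, yr); NA_real_ } else um / am
    rows[[yr]] <- data.frame(year = yr, density = unname(density_by_year[yr]),
                             used_mean = um, available_mean = am, ratio = ratio)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$density), ]
  rownames(out) <- NULL
  attr(out, "flagged_years") <- flagged
  out
}
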
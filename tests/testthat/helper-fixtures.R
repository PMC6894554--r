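# Shared fixtures, all generated in code.

unit_square <- function(x0 = 0, y0 = 0, side = 1) {
  polygon_xy(rbind(c(x0, y0), c(x0 + side, y0),
                   c(x0 + side, y0 + side), c(x0, y0 + side)))
}

# small recolonization world shared by several suites
small_world <- function(seed = 11, years = 8, extent = 120,
                        overlap_max = 0.3, K = 90, N0 = 8) {
  grid <- grid_spec(0, 0, extent, extent, 2)
  stack <- generate_landscape(grid, default_layer_specs(), seed = seed)
  history <- simulate_recolonization(
    stack, years = years, growth = list(N0 = N0, K = K, r = 0.4),
    territory_area_dist = list(mean_km2 = 250, sd_km2 = 80),
    overlap_schedule = seq(0, overlap_max, length.out = years),
    seed = seed + 1)
  list(grid = grid, stack = stack, history = history)
}

# simulated plain logistic data (no group structure in the truth)
logistic_data <- function(n, beta = c(-2, 1, -0.5), seed = 1,
                          n_packs = 20, n_years = 8, interaction = 0) {
  set.seed(seed)
  x1 <- rnorm(n); d <- rnorm(n)
  eta <- beta[1] + beta[2] * x1 + beta[3] * d + interaction * x1 * d
  data.frame(y = rbinom(n, 1, plogis(eta)), x1 = x1, wolf_density = d,
             pack_id = factor(sample(seq_len(n_packs), n, TRUE)),
             year = factor(sample(seq_len(n_years), n, TRUE)))
}
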
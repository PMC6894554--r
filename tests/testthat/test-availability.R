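test_that("overlap proportion matches direct polygon geometry", {
  a <- territory_record("A", 1, unit_square())
  b <- territory_record("B", 1, unit_square(x0 = 0.5))
  c3 <- territory_record("C", 1, unit_square(x0 = 5))
  expect_equal(overlap_proportion(list(a, c3)), 0)
  # two unit squares sharing half their area: 0.5 / 2 = 0.25
  expect_equal(overlap_proportion(list(a, b)), 0.25, tolerance = 1e-9)
  # disjoint trio plus one fully nested pair: intersection = nested area
  big <- territory_record("D", 1, unit_square(x0 = 10, side = 4))
  nest <- territory_record("E", 1, unit_square(x0 = 11, y0 = 1, side = 1))
  recs <- list(a, c3, territory_record("F", 1, unit_square(y0 = 5)), big, nest)
  tot <- 1 + 1 + 1 + 16 + 1
  expect_equal(overlap_proportion(recs), 1 / tot, tolerance = 1e-9)
  expect_error(overlap_proportion(list()), ">= 1 territory")
})

test_that("availability domains have the dispersal-buffer radius and exclusions", {
  k <- dispersal_kernel(1 / 55)
  # 95% of exponential dispersal distances fall inside 165 km
  expect_equal(k$q95, -55 * log(0.05), tolerance = 1e-12)
  expect_lt(k$q95, 165)
  g <- grid_spec(0, 0, 100, 100, 2)
  occ <- raster_new(g, 0)
  rec <- territory_record("A", 1, unit_square(x0 = 40, y0 = 40, side = 20))
  dom <- build_available_domain(rec, occ, k, overlap_allowance = 0)
  expect_equal(dom$radius_km, k$q95)
  # zero occupancy elsewhere: domain is the disc minus the own territory
  expect_true(all(dom$weight == 1))
  expect_true(all(dom$own[21:30, 21:30]))
  expect_false(any(dom$occ_other))
  # fully occupied landscape with no allowance is flagged
  occ1 <- raster_new(g, 1)
  expect_warning(build_available_domain(rec, occ1, k, overlap_allowance = 0),
                 "empty unused domain")
  far <- territory_record("B", 1, unit_square(x0 = 500, y0 = 500, side = 20))
  expect_error(build_available_domain(far, occ, k), "invalid record")
})

test_that("used-point allocation follows the one-per-50-km2 floor rule", {
  set.seed(2)
  # the printed mean territory of 283.10 km^2 yields five used points
  rec <- territory_record("A", 1, rescale_polygon(unit_square(side = 16), 283.10))
  expect_equal(nrow(draw_used(rec)), 5)
  tiny <- territory_record("B", 1, rescale_polygon(unit_square(side = 16), 49))
  expect_equal(nrow(draw_used(tiny)), 1)
  # containment over many draws
  pts <- do.call(rbind, replicate(50, draw_used(rec), simplify = FALSE))
  expect_true(all(poly_contains(rec$polygon, pts$x_km, pts$y_km)))
})

test_that("unused points follow the allowance split and inclusion weights", {
  g <- grid_spec(0, 0, 200, 200, 2)
  k <- dispersal_kernel()
  own <- unit_square(x0 = 90, y0 = 90, side = 20)
  rec <- territory_record("A", 1, own)
  # other occupied block on the right; unoccupied elsewhere
  occv <- matrix(0, 100, 100); occv[, 75:100] <- 1
  occ <- raster_new(g, occv)
  dom <- build_available_domain(rec, occ, k, overlap_allowance = 0.48)
  set.seed(9)
  reps <- replicate(60, {
    u <- draw_unused(dom, rate_km2 = 1000)
    c(mean(u$in_occupied), nrow(u))
  })
  expect_lt(abs(mean(reps[1, ]) - 0.48), 0.05)
  # count rule: one per 1000 km^2 of disc-minus-own geometric area
  eff <- sum(dom$in_disc & !dom$own) * grid_cell_area(g)
  expect_equal(unique(reps[2, ]), floor(eff / 1000))
  # zero-weight exclusion: with no allowance, no point lands on occupied ground
  dom0 <- build_available_domain(rec, occ, k, overlap_allowance = 0)
  u0 <- draw_unused(dom0, rate_km2 = 1000)
  expect_true(all(!u0$in_occupied))
  idx <- territorial:::grid_locate(g, u0$x_km, u0$y_km)
  expect_true(all(occv[cbind(idx$row, idx$col)] == 0))
})

test_that("the assembled sample table is complete, standardized and reproducible", {
  w <- small_world(seed = 81, years = 5, extent = 200)
  tel <- simulate_telemetry(w$history, stack = w$stack, fixes_per_pack_year = 60,
                            collared_fraction = 1, seed = 2)
  sv <- simulate_track_survey(w$history, seed = 3)
  sys <- list(stack = w$stack, history = w$history, telemetry = tel,
              survey = sv, grid = w$grid)
  run1 <- run_rspf_pipeline(sys, seed = 4, n_sim_occupancy = 8, fit = FALSE)
  run2 <- run_rspf_pipeline(sys, seed = 4, n_sim_occupancy = 8, fit = FALSE)
  expect_identical(run1$table, run2$table)
  tab <- run1$table
  covs <- c(names(w$stack$layers), "wolf_density")
  expect_false(anyNA(tab[, covs]))
  expect_true(all(tab$y %in% c(0, 1)))
  expect_true(all(c(0, 1) %in% tab$y))
  # pooled table-basis scalers keep full-table means near zero even though
  # per-year and used/unused subsets deviate
  for (nm in names(w$stack$layers)) expect_lt(abs(mean(tab[[nm]])), 0.2)
  for (nm in names(w$stack$layers)) expect_equal(sd(tab[[nm]]), 1, tolerance = 0.01)
  # used points lie inside their territory polygons
  used <- tab[tab$y == 1, ]
  ok <- mapply(function(pid, yr, x, y) {
    rec <- Filter(function(r) r$pack_id == pid,
                  run1$by_year[[as.character(yr)]])[[1]]
    poly_contains(rec$polygon, x, y)
  }, as.character(used$pack_id), as.character(used$year), used$x_km, used$y_km)
  expect_gte(mean(ok), 0.99)
})
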
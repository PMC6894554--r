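test_that("landscape layers honour sill, determinism and the zero-variance case", {
  g <- grid_spec(0, 0, 100, 100, 2)
  specs <- list(list(name = "a", spatial_range = 20, sill = 2),
                list(name = "flat", spatial_range = 20, sill = 0))
  st1 <- generate_landscape(g, specs, seed = 4)
  st2 <- generate_landscape(g, specs, seed = 4)
  expect_identical(st1$layers, st2$layers)
  expect_equal(sd(as.vector(st1$layers$a)), sqrt(2), tolerance = 1e-9)
  expect_true(all(st1$layers$flat == st1$layers$flat[1, 1]))
  expect_error(generate_landscape(g, list(list(name = "x", spatial_range = -1, sill = 1))),
               "invalid configuration")
})

test_that("empirical variogram approaches the sill beyond the correlation range", {
  g <- grid_spec(0, 0, 500, 500, 1)
  st <- generate_landscape(g, list(list(name = "z", spatial_range = 20, sill = 1.5)),
                           seed = 9)
  z <- st$layers$z
  # Monte-Carlo variogram oracle at a lag far beyond the range
  set.seed(10)
  lag <- 80L
  i <- sample(1:(500 - lag), 20000, TRUE)
  j <- sample(1:500, 20000, TRUE)
  semiv <- mean((z[cbind(i, j)] - z[cbind(i + lag, j)])^2) / 2
  expect_lt(abs(semiv - 1.5) / 1.5, 0.25)
})

test_that("recolonization follows logistic growth, IPD ordering and the overlap schedule", {
  w <- small_world(seed = 21)
  h <- w$history
  expect_true(all(h$abundance <= h$growth$K + 1e-9))
  expect_true(all(diff(h$abundance) >= -1e-9))
  expect_true(all(vapply(h$packs[[length(h$years)]],
                         function(r) r$size >= 2, TRUE)))
  # single founding territory has zero overlap
  expect_equal(h$realized_overlap[1], 0, tolerance = 0.02)
  # realized overlap tracks the schedule
  late <- length(h$years)
  expect_lt(abs(h$realized_overlap[late] - h$overlap_schedule[late]), 0.08)

  # IPD: settlement order decreasing in true suitability at the centre
  rho <- vapply(1:6, function(s) {
    ww <- small_world(seed = 100 + s)
    st <- true_suitability(ww$stack)
    recs <- ww$history$packs[[length(ww$history$years)]]
    sy <- vapply(recs, function(r) r$settle_year, 0)
    sv <- vapply(recs, function(r) raster_extract(st, r$center[1], r$center[2]), 0)
    suppressWarnings(cor(sy, sv, method = "spearman"))
  }, 0)
  expect_lt(mean(rho), 0)
  expect_gt(mean(rho < 0), 0.8)
})

test_that("disjoint schedules give pairwise-disjoint territories", {
  w <- small_world(seed = 31, overlap_max = 0, years = 6)
  recs <- w$history$packs[[6]]
  for (i in seq_along(recs)) for (j in seq_len(i - 1)) {
    expect_lt(poly_intersection_area(recs[[i]]$polygon, recs[[j]]$polygon), 1e-6)
  }
})

test_that("telemetry respects counts, containment and the collared fraction", {
  w <- small_world(seed = 41)
  locs <- simulate_telemetry(w$history, stack = w$stack, fixes_per_pack_year = 52,
                             collared_fraction = 1, error_sd_km = 0.2, seed = 5)
  # exact count contract per collared pack-year
  counts <- table(locs$pack_id, locs$year)
  expect_true(all(counts[counts > 0] == 52))
  # containment: >= 95% of fixes inside the true polygon
  inside <- mapply(function(pid, yr, x, y) {
    rec <- Filter(function(r) r$pack_id == pid, w$history$packs[[yr]])[[1]]
    poly_contains(rec$polygon, x, y)
  }, locs$pack_id, locs$year, locs$x_km, locs$y_km)
  expect_gte(mean(inside), 0.95)
  # no collars, no fixes
  none <- simulate_telemetry(w$history, collared_fraction = 0, seed = 5)
  expect_equal(nrow(none), 0)
})

test_that("track survey matrix reflects detection, gaps and sizes", {
  w <- small_world(seed = 51)
  sv <- simulate_track_survey(w$history, detection_prob = 1,
                              panel_gap_years = c(4L, 6L), seed = 2)
  m <- sv$matrix
  expect_true(all(is.na(m[, "4"])))
  expect_true(all(is.na(m[, "6"])))
  # perfect detection outside gaps: matrix equals true occupancy/sizes
  for (t in c(3, 5, 8)) {
    truth <- w$history$packs[[t]]
    for (rec in truth) expect_equal(unname(m[rec$pack_id, as.character(t)]), rec$size)
    absent <- setdiff(rownames(m), vapply(truth, function(r) r$pack_id, ""))
    expect_true(all(m[absent, as.character(t)] == 0))
  }
  # detections are binomial at the configured probability
  sv8 <- simulate_track_survey(w$history, detection_prob = 0.8, seed = 3)
  pres <- 0L; det <- 0L
  for (t in w$history$years) {
    for (rec in w$history$packs[[t]]) {
      pres <- pres + 1L
      if (!is.na(sv8$matrix[rec$pack_id, as.character(t)]) &&
          sv8$matrix[rec$pack_id, as.character(t)] >= 2) det <- det + 1L
    }
  }
  expect_lt(abs(det / pres - 0.8), 0.07)
  # at least 3 track points per detected pack (MCP feasibility)
  tcounts <- table(sv$tracks$pack_id, sv$tracks$year)
  expect_true(all(tcounts[tcounts > 0] >= 3))
})
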
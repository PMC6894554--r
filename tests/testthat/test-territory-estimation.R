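test_that("outlier screening removes only genuinely far points", {
  set.seed(2)
  th <- runif(99, 0, 2 * pi); r <- sqrt(runif(99))
  locs <- data.frame(x_km = r * cos(th), y_km = r * sin(th))
  locs <- rbind(locs, data.frame(x_km = 100, y_km = 0))
  kept <- remove_outliers(locs, k = 6)
  expect_equal(nrow(kept), 99)
  expect_false(100 %in% kept$x_km)
  # order-preserving subset
  expect_true(all(diff(match(paste(kept$x_km, kept$y_km),
                             paste(locs$x_km, locs$y_km))) > 0))
  # zero spread: nothing removed
  coin <- data.frame(x_km = rep(1, 10), y_km = rep(2, 10))
  expect_equal(nrow(remove_outliers(coin)), 10)
  expect_error(remove_outliers(coin[1:2, ]), "too few")
})

test_that("kernel UD integrates to one and matches the normal density oracle", {
  set.seed(5)
  locs <- data.frame(x_km = rnorm(1000), y_km = rnorm(1000))
  ud <- fit_kernel_ud(locs, bandwidth_method = "normal_reference", cell = 0.25)
  expect_equal(sum(ud$mass), 1, tolerance = 1e-6)
  # density at the origin of a standard bivariate normal is 1/(2*pi)
  d0 <- raster_extract(raster_new(ud$grid, ud$density), 0, 0)
  expect_lt(abs(d0 - 1 / (2 * pi)) / (1 / (2 * pi)), 0.15)
  # reference rule scale equivariance: doubling coordinates doubles sds
  ud2 <- fit_kernel_ud(transform(locs, x_km = 2 * x_km, y_km = 2 * y_km),
                       bandwidth_method = "normal_reference", cell = 0.5)
  expect_equal(sqrt(diag(ud2$bandwidth)), 2 * sqrt(diag(ud$bandwidth)),
               tolerance = 1e-9)
  expect_error(fit_kernel_ud(locs[1:10, ]), "too few")
  degen <- data.frame(x_km = 1:40, y_km = (1:40) * 2)
  expect_error(fit_kernel_ud(degen), "degenerate")
})

test_that("the 95% isopleth of a Gaussian UD matches the chi-square ellipse", {
  set.seed(6)
  locs <- data.frame(x_km = rnorm(4000), y_km = rnorm(4000))
  ud <- fit_kernel_ud(locs, bandwidth_method = "normal_reference", cell = 0.2)
  iso <- extract_isopleth(ud, 0.95)
  # closed form: area of the 95% probability ellipse of a unit bivariate
  # normal is pi * qchisq(0.95, 2) = pi * 5.991
  expect_lt(abs(poly_area(iso) - pi * qchisq(0.95, 2)) / (pi * qchisq(0.95, 2)), 0.12)
  # mass contract and monotonicity in level
  expect_gte(sum(ud$mass[poly_rasterize(iso, ud$grid)]), 0.95)
  a50 <- poly_area(extract_isopleth(ud, 0.5))
  a99 <- poly_area(extract_isopleth(ud, 0.99))
  expect_true(a50 < poly_area(iso) && poly_area(iso) < a99)
})

test_that("minimum convex polygon matches direct geometry", {
  sq <- data.frame(x_km = c(0, 1, 1, 0), y_km = c(0, 0, 1, 1))
  expect_equal(poly_area(minimum_convex_polygon(sq)), 1)
  line <- data.frame(x_km = 1:5, y_km = 2 * (1:5))
  expect_error(minimum_convex_polygon(line), "degenerate")
})

test_that("the estimation cascade assigns methods in the documented order", {
  set.seed(8)
  mk_fixes <- function(pid, yr, n, cx, cy)
    data.frame(pack_id = pid, year = yr,
               x_km = cx + rnorm(n, sd = 3), y_km = cy + rnorm(n, sd = 3))
  # P1: 52 fixes in every year -> A-yearly
  # P2: 12 fixes per year -> pooled window of 36 -> A-window
  # P3: telemetry only in year 1, present through year 3 -> the year-3
  #     window (years 2-4) is empty, so the prior estimate carries (A)
  # P4: no telemetry, 5 track points -> C in every year
  tel <- rbind(mk_fixes("P1", 1, 52, 10, 10), mk_fixes("P1", 2, 52, 10, 10),
               mk_fixes("P2", 1, 12, 40, 10), mk_fixes("P2", 2, 12, 40, 10),
               mk_fixes("P2", 3, 12, 40, 10),
               mk_fixes("P3", 1, 52, 10, 40))
  trk <- data.frame(pack_id = "P4", year = 1,
                    x_km = c(40, 44, 42, 40, 44), y_km = c(40, 40, 44, 43, 43))
  pm <- matrix(c(4, 4, 4,  3, 3, 3,  4, 4, 4,  2, 2, 2), nrow = 4, byrow = TRUE,
               dimnames = list(c("P1", "P2", "P3", "P4"), 1:3))
  recs <- estimate_territories(tel, trk, pm, min_locs = 30)
  tags <- sapply(recs, function(r) r$method_tag)
  ids <- sapply(recs, function(r) paste0(r$pack_id, ".", r$year))
  expect_equal(unname(tags[ids == "P1.1"]), "A-yearly")
  expect_equal(unname(tags[ids == "P2.2"]), "A-window")
  expect_equal(unname(tags[ids == "P3.3"]), "A")
  expect_equal(unname(tags[ids == "P4.2"]), "C")
  expect_equal(length(attr(recs, "unresolved")), 0)
})

test_that("estimated isopleths recover true territories on synthetic packs", {
  w <- small_world(seed = 61, years = 6, K = 60)
  tel <- simulate_telemetry(w$history, stack = w$stack, fixes_per_pack_year = 70,
                            collared_fraction = 1, seed = 7)
  sv <- simulate_track_survey(w$history, seed = 8)
  recs <- estimate_territories(tel, sv$tracks, sv$matrix, min_locs = 30)
  jac <- vapply(recs, function(r) {
    truth <- Filter(function(x) x$pack_id == r$pack_id, w$history$packs[[r$year]])[[1]]
    g <- grid_spec(floor(min(poly_bbox(r$polygon)[1], poly_bbox(truth$polygon)[1])) - 4,
                   floor(min(poly_bbox(r$polygon)[2], poly_bbox(truth$polygon)[2])) - 4,
                   ceiling(max(poly_bbox(r$polygon)[3], poly_bbox(truth$polygon)[3])) + 4,
                   ceiling(max(poly_bbox(r$polygon)[4], poly_bbox(truth$polygon)[4])) + 4, 0.5)
    poly_jaccard(r$polygon, truth$polygon, g)
  }, 0)
  expect_gte(median(jac), 0.5)
})
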
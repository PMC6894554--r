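test_that("polygon rescaling hits target areas exactly enough", {
  sq <- unit_square()
  # closed form: growing a unit square to area 4 is an offset of 0.5 per side
  r <- rescale_polygon(sq, 4)
  expect_equal(poly_area(r), 4, tolerance = 0.01)
  expect_equal(poly_bbox(r), c(-0.5, -0.5, 1.5, 1.5), tolerance = 0.02)
  # identity
  expect_identical(rescale_polygon(sq, 1), sq)
  # random convex polygons, growth and shrinkage, within 1%
  set.seed(12)
  for (i in 1:100) {
    ctr <- runif(2, 0, 50)
    pts <- cbind(ctr[1] + runif(7, -5, 5), ctr[2] + runif(7, -5, 5))
    p <- polygon_xy(pts[grDevices::chull(pts), ])
    target <- poly_area(p) * runif(1, 0.4, 2.5)
    expect_lt(abs(poly_area(rescale_polygon(p, target)) - target) / target, 0.01)
  }
  # unreachable erosion returns the 10% floor with a warning
  expect_warning(small <- rescale_polygon(sq, 0.01), "10%")
  expect_equal(poly_area(small), 0.1, tolerance = 0.02)
})

test_that("territory area resampling follows pack- and population-level normals", {
  sq <- unit_square(side = 16)
  recs <- lapply(1:3, function(t)
    territory_record("A", t, rescale_polygon(sq, 250 + 10 * t), method_tag = "A-yearly"))
  pop <- territory_area_stats(recs)
  # pack sd = 0 degenerates to the mean every draw
  one <- territory_record("B", 1, sq, method_tag = "A-yearly")
  expect_equal(sample_territory_area(one, list(one, one), list(mean = 99, sd = 0)),
               poly_area(sq))
  # method C pack draws from the population stats
  cpack <- territory_record("C1", 1, sq, method_tag = "C")
  set.seed(3)
  draws <- replicate(1000, sample_territory_area(cpack, list(cpack), pop))
  se <- pop$sd / sqrt(1000)
  expect_lt(abs(mean(draws) - pop$mean), max(2 * se, 0.02 * pop$mean))
  # truncation floor at 10% of the mean
  set.seed(4)
  lows <- replicate(2000, sample_territory_area(cpack, list(cpack),
                                                list(mean = 100, sd = 400)))
  expect_gte(min(lows), 10)
})

test_that("occupancy rasters average binary replicates and respect degeneracy", {
  g <- grid_spec(0, 0, 40, 40, 1)
  sq <- polygon_xy(rbind(c(10, 10), c(30, 10), c(30, 30), c(10, 30)))
  rec <- territory_record("A", 1, sq, method_tag = "A-yearly")
  # one record, sd 0 (single pack-year history): binary baseline occupancy
  occ0 <- occupancy_probability(list(rec), g, n_sim = 20, seed = 5)
  expect_true(all(occ0$values %in% c(0, 1)))
  expect_equal(occ0$values, poly_rasterize(sq, g) * 1)
  # n_sim = 1 is binary by construction
  recs <- lapply(1:3, function(t)
    territory_record("A", t, rescale_polygon(sq, 400 * c(0.8, 1, 1.2)[t]),
                     method_tag = "A-yearly"))
  occ1 <- occupancy_probability(list(recs[[2]]), g, n_sim = 1,
                                all_records = recs, seed = 6)
  expect_true(all(occ1$values %in% c(0, 1)))
  # values are multiples of 1/n_sim in [0, 1]
  occ <- occupancy_probability(list(recs[[2]]), g, n_sim = 25,
                               all_records = recs, seed = 7)
  expect_true(all(occ$values >= 0 & occ$values <= 1))
  expect_true(all(abs(occ$values * 25 - round(occ$values * 25)) < 1e-9))
  # the centroid cell survives +/- sd area perturbations
  expect_gte(raster_extract(occ, 20, 20), 0.95)
  # fixed seed reproduces bit-identically
  occ_b <- occupancy_probability(list(recs[[2]]), g, n_sim = 25,
                                 all_records = recs, seed = 7)
  expect_identical(occ$values, occ_b$values)
  # empty year gives an all-zero raster
  expect_true(all(occupancy_probability(list(), g, n_sim = 5)$values == 0))
})

test_that("enlarging mean areas never decreases occupancy (common random numbers)", {
  g <- grid_spec(0, 0, 40, 40, 1)
  sq <- polygon_xy(rbind(c(12, 12), c(28, 12), c(28, 28), c(12, 28)))
  base <- lapply(1:3, function(t)
    territory_record("A", t, rescale_polygon(sq, 220 + 20 * t), method_tag = "A-yearly"))
  big <- lapply(base, function(r) {
    r2 <- territory_record(r$pack_id, r$year, rescale_polygon(r$polygon, r$area_km2 * 1.6),
                           method_tag = r$method_tag)
    r2
  })
  o1 <- occupancy_probability(list(base[[2]]), g, n_sim = 30, all_records = base, seed = 9)
  o2 <- occupancy_probability(list(big[[2]]), g, n_sim = 30, all_records = big, seed = 9)
  expect_true(all(o2$values - o1$values >= -1e-9))
})
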
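test_that("blueprint invariants are enforced", {
  expect_error(city_blueprint(side_m = 505), "divisible")
  expect_error(city_blueprint(coarse_res_m = 10, fine_res_m = 3), "divisible")
  expect_error(city_blueprint(class_mix = c(garden = 0.5)), "sum to 1")
  expect_error(city_blueprint(pop_total = -1), "non-negative")
})

test_that("a degenerate single-class mix yields a uniform raster", {
  bp <- city_blueprint(side_m = 300, class_mix = c(garden = 1), pop_total = 0)
  lulc <- make_lulc(bp)
  expect_true(all(lulc == base_classes[["garden"]]))
})

test_that("LULC generation is deterministic and covers all classes", {
  bp <- city_blueprint(side_m = 500, seed = 0)
  a <- make_lulc(bp)
  b <- make_lulc(bp)
  expect_identical(a, b)
  present <- names(base_classes)[base_classes %in% unique(as.vector(a))]
  expect_setequal(present, names(base_classes))
  # every candidate base class has at least one pixel
  expect_true(all(candidate_classes %in% present))
})

test_that("realized class fractions track the mix on the default city", {
  city <- default_city()
  frac <- table(factor(names(base_classes)[match(city$lulc, base_classes)],
                       levels = names(base_classes))) / length(city$lulc)
  mix <- default_class_mix()
  expect_true(all(abs(frac[names(mix)] - mix) <= 0.05))
})

test_that("masks honour degenerate landscapes", {
  bpw <- city_blueprint(side_m = 300, class_mix = c(water = 1), pop_total = 0)
  lw <- make_lulc(bpw)
  mw <- make_masks(lw, bpw)
  expect_true(all(mw$tree == 0))
  expect_true(all(mw$building == 0))

  bpf <- city_blueprint(side_m = 300, class_mix = c(forest = 1),
                        pop_total = 0)
  lf <- make_lulc(bpf)
  mf <- make_masks(lf, bpf)
  expect_gte(mean(mf$tree), 0.75)
})

test_that("masks are binary, reproducible and non-overlapping", {
  bp <- city_blueprint(side_m = 400, seed = 5)
  lulc <- make_lulc(bp)
  m1 <- make_masks(lulc, bp)
  m2 <- make_masks(lulc, bp)
  expect_identical(m1, m2)
  expect_true(all(m1$tree %in% c(0L, 1L)))
  expect_true(all(m1$building %in% c(0L, 1L)))
  expect_true(all(m1$tree + m1$building <= 1L))

  # building mask covers most of each building pixel, none of the water
  bfrac <- cover_fractions(m1$building, 10)
  bld <- lulc == base_classes[["building"]]
  expect_gte(mean(bfrac[bld]), 0.75)
  expect_equal(max(bfrac[lulc == base_classes[["water"]]]), 0)
})

test_that("tree-mask density is ordered forest > garden > roads", {
  city <- small_city()
  tfrac <- cover_fractions(city$tree_mask, 10)
  cls <- matrix(names(base_classes)[match(city$lulc, base_classes)],
                nrow(city$lulc))
  expect_gt(mean(tfrac[cls == "forest"]), mean(tfrac[cls == "garden"]))
  expect_gt(mean(tfrac[cls == "garden"]), mean(tfrac[cls == "road_path"]))
})

test_that("mask cover agrees with generator targets within 0.1 MAE", {
  city <- default_city()
  tfrac <- cover_fractions(city$tree_mask, 10)
  cls <- names(base_classes)[match(city$lulc, base_classes)]
  targets <- canopycool:::tree_density_by_class
  for (c in names(targets)) {
    v <- tfrac[cls == c]
    if (length(v) > 0)
      expect_lte(mean(abs(v - targets[[c]])), 0.1)
  }
})

test_that("population conserves the total and concentrates on buildings", {
  city <- small_city()
  pop <- city$population
  expect_identical(sum(pop), city$blueprint$pop_total)
  expect_true(all(pop >= 0))

  # share on cells containing building pixels
  bmask <- (city$lulc == base_classes[["building"]]) * 1
  bcells <- block_aggregate(bmask, 10) > 0
  expect_gte(sum(pop[bcells]) / sum(pop), 0.8)

  expect_true(all(make_population(city$lulc, 0, seed = 1) == 0))
  p1 <- make_population(city$lulc, 1000, seed = 1)
  p2 <- make_population(city$lulc, 1000, seed = 2)
  expect_equal(sum(p1), sum(p2))
  expect_false(identical(p1, p2))
})

test_that("population placement fails without buildings", {
  bp <- city_blueprint(side_m = 300, class_mix = c(forest = 1),
                       pop_total = 10)
  lulc <- make_lulc(bp)
  expect_error(make_population(lulc, 10), "building")
})

test_that("station series is deterministic, admissible and validated", {
  expect_error(make_station_series(n_stations = 1), "at least 2")
  s1 <- make_station_series(seed = 4)
  s2 <- make_station_series(seed = 4)
  expect_identical(s1, s2)
  day_min <- tapply(s1$temp_21h_c, s1$date, min)
  expect_gt(max(day_min), 20)
})
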
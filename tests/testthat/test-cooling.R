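test_that("Hargreaves ET0 follows the temperature-based formula", {
  expect_equal(hargreaves_et0(20, 20, 20, 12), 0)
  expect_equal(hargreaves_et0(15, 22.2, 30, 12),
               0.0023 * 12 * (22.2 + 17.8) * sqrt(15))
  expect_equal(hargreaves_et0(-20, -17.8, -10, 12), 0)
  expect_error(hargreaves_et0(25, 22, 20, 12), "invalid day")
})

test_that("reference-day selection maximizes spread above the floor", {
  one <- data.frame(date = "2018-07-27", station_id = c("a", "b"),
                    temp_21h_c = c(20.60, 28.08))
  rd <- select_reference_day(one)
  expect_equal(rd$t_ref, 20.60)
  expect_equal(rd$uhi_max, 7.48)

  # a bigger spread on an inadmissible (cool) day loses
  two <- data.frame(date = rep(c("d1", "d2"), each = 2),
                    station_id = rep(c("a", "b"), 2),
                    temp_21h_c = c(21, 26, 19, 28))
  rd2 <- select_reference_day(two)
  expect_equal(rd2$day, "d1")
  expect_equal(rd2$uhi_max, 5)

  flat <- data.frame(date = "d", station_id = c("a", "b"),
                     temp_21h_c = c(25, 25))
  expect_equal(select_reference_day(flat)$uhi_max, 0)

  cold <- data.frame(date = "d", station_id = c("a", "b"),
                     temp_21h_c = c(15, 25))
  expect_error(select_reference_day(cold), "no admissible day")
  expect_error(select_reference_day(one[1, ]), "2 stations")
})

test_that("cooling capacity is the weighted mechanism sum", {
  expect_equal(cooling_capacity(1, 1, 1), 1.0)
  expect_equal(cooling_capacity(0, 0, 0), 0.0)
  expect_equal(cooling_capacity(0.875, 0.20, 0.5), 0.665)
  expect_error(cooling_capacity(1, 1, 1, weights = c(shade = 0.5,
                                                     albedo = 0.5,
                                                     eti = 0.5)),
               "sum to 1")
})

test_that("evapotranspiration index is normalized and clipped", {
  expect_equal(eti_index(1, 5, 10), 0.5)
  expect_equal(eti_index(2, 10, 5), 1)
  expect_equal(eti_index(0, 10, 5), 0)
  expect_error(eti_index(1, 5, 0), "positive")
})

test_that("heat mitigation without green areas is the cooling capacity", {
  cc <- matrix(runif(25), 5, 5)
  hm <- heat_mitigation(cc, matrix(FALSE, 5, 5), res = 10)
  expect_identical(hm, cc)
})

test_that("a large uniform green patch is a fixed point", {
  cc <- matrix(0.9, 10, 10)
  g <- matrix(TRUE, 10, 10)
  p <- climate_params(green_area_min = 0.5)
  hm <- heat_mitigation(cc, g, res = 10, params = p)
  expect_equal(hm, cc)
})

test_that("patches below the area threshold have no park effect", {
  cc <- matrix(0.1, 9, 9)
  g <- matrix(FALSE, 9, 9)
  g[5, 5] <- TRUE  # 0.01 ha << 2 ha
  cc[5, 5] <- 1
  hm <- heat_mitigation(cc, g, res = 10, params = climate_params())
  expect_identical(hm, cc)
})

test_that("heat mitigation matches the all-pairs brute force", {
  set.seed(42)
  p <- climate_params(green_area_min = 0.03)
  for (i in 1:3) {
    n <- sample(10:16, 1)
    cc <- matrix(runif(n * n), n, n)
    g <- matrix(runif(n * n) < 0.2, n, n)
    hm <- heat_mitigation(cc, g, res = 10, params = p)
    expect_equal(hm, bf_heat_mitigation(cc, g, 10, p), tolerance = 1e-12)
  }
})

test_that("temperature mapping and blending respect the bounds", {
  p <- climate_params(t_ref = 20.60, uhi_max = 7.48)
  t1 <- temperature_map(matrix(1, 12, 12), p)
  expect_true(all(abs(t1$t_air - 20.60) < 1e-12))
  t0 <- temperature_map(matrix(0, 12, 12), p)
  expect_true(all(abs(t0$t_air - 28.08) < 1e-12))

  th <- temperature_map(matrix(0.37, 12, 12), p)
  expect_true(all(abs(th$t_air - th$t_air[1, 1]) < 1e-12))

  set.seed(7)
  hm <- matrix(runif(400), 20, 20)
  tf <- temperature_map(hm, p)
  expect_true(all(tf$t_air >= p$t_ref - 1e-9))
  expect_true(all(tf$t_air <= p$t_ref + p$uhi_max + 1e-9))
  expect_error(temperature_map(matrix(1.5, 2, 2), p), "\\[0, 1\\]")
})

test_that("a uniform landscape simulates to a uniform temperature", {
  base <- matrix(base_classes[["water"]], 8, 8)
  r <- refine_lulc(base, matrix(0, 8, 8), matrix(0, 8, 8))
  tab <- biophysical_table(r)
  tf <- simulate_temperature(r, tab, et0 = 5)
  expect_lt(diff(range(tf$t_air)), 1e-12)
})

test_that("greening never warms any pixel", {
  r <- small_refined()
  tab <- biophysical_table(r)
  base_tf <- simulate_temperature(r, tab, et0 = 5)
  cand <- find_candidates(r)
  for (s in c("random", "cluster", "scatter")) {
    scn <- apply_scenario(r, sample_pixels(cand, r,
                                           scenario_config(0.5, s, 11)))
    tf <- simulate_temperature(scn, tab, et0 = 5)
    expect_true(all(tf$t_air <= base_tf$t_air + 1e-9))
    expect_lte(tf$t_bar, base_tf$t_bar)
  }
})

test_that("coarse ET0 rasters are resampled to the grid", {
  r <- small_refined()
  tab <- biophysical_table(r)
  et0_coarse <- matrix(seq(3, 6, length.out = 25), 5, 5)
  tf <- simulate_temperature(r, tab, et0 = et0_coarse)
  expect_true(all(is.finite(tf$t_air)))
  expect_true(all(tf$t_air >= climate_params()$t_ref - 1e-9))
})

test_that("a missing refined code is reported", {
  r <- small_refined()
  tab <- biophysical_table(r)
  expect_error(simulate_temperature(r, tab[tab$code != r$codes[1, 1], ],
                                    et0 = 5),
               "missing from the biophysical table")
})
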
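test_that("candidate rules: class list, building cover, road adjacency", {
  n <- 6
  base <- matrix(base_classes[["garden"]], n, n)
  base[, 3] <- base_classes[["road_path"]]
  base[1, 1] <- base_classes[["forest"]]
  base[2, 1] <- base_classes[["water"]]
  tfrac <- matrix(0.3, n, n)
  bfrac <- matrix(0, n, n)
  bfrac[4, 1] <- 0.30      # building cover over 25%: excluded
  tfrac[5, 1] <- 0.80      # already high canopy: excluded
  r <- refine_lulc(base, tfrac, bfrac)
  cand <- find_candidates(r)
  key <- paste(cand$row, cand$col)
  expect_false("1 1" %in% key)  # forest
  expect_false("2 1" %in% key)  # water
  expect_false("4 1" %in% key)  # building bin > 0
  expect_false("5 1" %in% key)  # tree bin already 3
  expect_true("6 1" %in% key)   # plain garden
  expect_true("1 3" %in% key)   # road next to garden
  expect_identical(anyDuplicated(key), 0L)
})

test_that("mid-road pixels (all-road Moore neighbourhood) are excluded", {
  n <- 5
  base <- matrix(base_classes[["road_path"]], n, n)
  base[, 5] <- base_classes[["garden"]]
  r <- refine_lulc(base, matrix(0, n, n), matrix(0, n, n))
  cand <- find_candidates(r)
  key <- paste(cand$row, cand$col)
  # column 2's interior pixels see only roads around them
  expect_false("3 2" %in% key)
  # column 4 borders the garden column
  expect_true("3 4" %in% key)
  # border pixels of column 1 see only in-bounds road neighbours: excluded
  expect_false("1 1" %in% key)
})

test_that("sampling returns the exact count and is seeded", {
  r <- toy_refined(10)
  cand <- find_candidates(r)
  n <- attr(cand, "total_count")
  cfg <- scenario_config(0.25, "random", run_seed = 9)
  px1 <- sample_pixels(cand, r, cfg)
  px2 <- sample_pixels(cand, r, cfg)
  expect_identical(px1, px2)
  expect_identical(nrow(px1), as.integer(floor(0.25 * n + 0.5)))
  px3 <- sample_pixels(cand, r, scenario_config(0.25, "random", 10))
  expect_false(identical(rownames(px1), rownames(px3)))
})

test_that("proportion 1 transforms every candidate for any strategy/seed", {
  r <- toy_refined(8)
  cand <- find_candidates(r)
  sets <- lapply(c("random", "cluster", "scatter"), function(s)
    sample_pixels(cand, r, scenario_config(1, s, run_seed = s == "random")))
  expect_identical(sets[[1]], sets[[2]])
  expect_identical(sets[[2]], sets[[3]])
  expect_identical(nrow(sets[[1]]), attr(cand, "total_count"))
})

test_that("scenarios at increasing proportions are nested", {
  r <- small_refined()
  cand <- find_candidates(r)
  for (s in c("random", "cluster", "scatter")) {
    k1 <- paste(sample_pixels(cand, r, scenario_config(0.25, s, 3))$row,
                sample_pixels(cand, r, scenario_config(0.25, s, 3))$col)
    big <- sample_pixels(cand, r, scenario_config(0.75, s, 3))
    expect_true(all(k1 %in% paste(big$row, big$col)))
  }
})

test_that("tiny proportions warn and return an empty set", {
  r <- toy_refined(4)
  cand <- find_candidates(r)
  expect_warning(px <- sample_pixels(cand, r,
                                     scenario_config(1e-6, "random", 1)),
                 "zero pixels")
  expect_identical(nrow(px), 0L)
})

test_that("cluster picks the candidate with most high-canopy neighbours", {
  # a 3-cell high-canopy block giving one candidate 3 Moore neighbours
  high <- rbind(c(1, 1), c(1, 2), c(2, 1))
  r <- toy_refined(6, high = high)
  cand <- find_candidates(r)
  ord <- candidate_order(cand, r, "cluster", seed = 1)
  first <- cand[ord[1], ]
  expect_identical(c(first$row, first$col), c(2L, 2L))
  # scatter defers that same pixel
  ords <- candidate_order(cand, r, "scatter", seed = 1)
  firsts <- cand[ords[1], ]
  expect_false(identical(c(firsts$row, firsts$col), c(2L, 2L)))
})

test_that("dynamic clustering grows contiguously from the canopy seed", {
  high <- cbind(3, 3)
  r <- toy_refined(7, high = high)
  cand <- find_candidates(r)
  ord <- candidate_order(cand, r, "cluster", seed = 2)
  picked <- cbind(3L, 3L)  # the initial high-canopy pixel
  for (k in seq_len(20)) {
    p <- as.integer(cand[ord[k], c("row", "col")])
    adj <- any(abs(picked[, 1] - p[1]) <= 1 & abs(picked[, 2] - p[2]) <= 1)
    expect_true(adj)
    picked <- rbind(picked, p)
  }
})

test_that("apply_scenario raises the tree bin and nothing else", {
  base <- matrix(base_classes[["sidewalk"]], 2, 2)
  r <- refine_lulc(base, matrix(c(0.3, 0, 0, 0), 2, 2), matrix(0, 2, 2))
  out <- apply_scenario(r, data.frame(row = 1, col = 1))
  expect_equal(out$codes[1, 1], base_classes[["sidewalk"]] * 100L + 30L)
  expect_equal(out$codes[2, 1], r$codes[2, 1])

  expect_identical(apply_scenario(r, data.frame(row = integer(0),
                                                col = integer(0)))$codes,
                   r$codes)
  twice <- apply_scenario(out, data.frame(row = 1, col = 1))
  expect_identical(twice$codes, out$codes)
  expect_error(apply_scenario(r, data.frame(row = 5, col = 1)), "extent")
})

test_that("per-class tallies conserve the pixel count", {
  r <- small_refined()
  cand <- find_candidates(r)
  px <- sample_pixels(cand, r, scenario_config(0.5, "random", 1))
  tly <- tally_by_class(px, r)
  expect_identical(sum(tly), nrow(px))
  expect_identical(unname(tly[["water"]]), 0L)
  empty <- tally_by_class(px[0, ], r)
  expect_true(all(empty == 0L))
})
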
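#' Blueprint for a synthetic city
#'
#' Describes the synthetic urban landscape from which all pipeline inputs are
#' generated: a square extent, a coarse LULC grid, fine binary tree/building
#' masks, a 100 m population grid and a station temperature series. The
#' layout is concentric: a dense core of buildings, roads and sidewalks, a
#' garden-rich residential ring, a forest periphery, and a water body along
#' the western edge.
#'
#' @param side_m Extent side in metres. Must be divisible by `coarse_res_m`
#'   and by 100 (the population grid resolution).
#' @param coarse_res_m Coarse (LULC) cell size in metres.
#' @param fine_res_m Fine (mask) cell size in metres; must divide
#'   `coarse_res_m`.
#' @param class_mix Named numeric vector of target areal fractions per base
#'   class (names from [base_classes]); must sum to 1.
#' @param pop_total Total number of inhabitants to distribute.
#' @param seed Integer seed; all generator output is a pure function of the
#'   blueprint (including this seed).
#' @return An object of class `city_blueprint`.
#' @export
city_blueprint <- function(side_m = 2500,
                           coarse_res_m = 10,
                           fine_res_m = 1,
                           class_mix = default_class_mix(),
                           pop_total = 50000,
                           seed = 0L) {
  if (side_m %% coarse_res_m != 0)
    stop("side_m must be divisible by coarse_res_m")
  if (coarse_res_m %% fine_res_m != 0)
    stop("coarse_res_m must be divisible by fine_res_m")
  if (abs(sum(class_mix) - 1) > 1e-9)
    stop("class fractions must sum to 1")
  if (any(class_mix < 0)) stop("class fractions must be non-negative")
  if (!all(names(class_mix) %in% names(base_classes)))
    stop("unknown class in class_mix: ",
         paste(setdiff(names(class_mix), names(base_classes)), collapse = ", "))
  if (pop_total < 0) stop("pop_total must be non-negative")
  n <- side_m %/% coarse_res_m
  if (n * n < sum(class_mix > 0))
    stop("extent too small to place all classes")
  structure(list(side_m = side_m, coarse_res_m = coarse_res_m,
                 fine_res_m = fine_res_m, class_mix = class_mix,
                 pop_total = as.integer(pop_total), seed = as.integer(seed)),
            class = "city_blueprint")
}

#' Default class mix of the synthetic city
#'
#' Areal fractions loosely patterned on a mid-size European agglomeration
#' with a lake shore and a forested periphery.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_class_mix <- function() {
  c(water = 0.05, forest = 0.22, garden = 0.27, building = 0.15,
    road_path = 0.11, sidewalk = 0.08, traffic_island = 0.02,
    other_impervious = 0.10)
}

#' Generate the coarse LULC raster of a synthetic city
#'
#' Deterministic given the blueprint. Water fills the western edge, forest
#' the periphery (by jittered distance from the urban centre), roads form a
#' connected grid of corridors through the urban area plus one wide
#' "highway" band, sidewalks and traffic islands attach to roads, buildings
#' concentrate towards the centre, and garden fills the rest. Realized class
#' fractions track `class_mix` to within a few percentage points.
#'
#' @param blueprint A [city_blueprint()].
#' @return Integer matrix of base class codes with attribute `res`
#'   (cell size, m).
#' @export
make_lulc <- function(blueprint) {
  stopifnot(inherits(blueprint, "city_blueprint"))
  set.seed(blueprint$seed)
  n <- blueprint$side_m %/% blueprint$coarse_res_m
  N <- n * n
  mix <- numeric(length(base_classes))
  names(mix) <- names(base_classes)
  mix[names(blueprint$class_mix)] <- blueprint$class_mix

  quota <- round(mix * N)
  # make quotas sum to N by adjusting the largest class
  imax <- which.max(quota)
  quota[imax] <- quota[imax] + (N - sum(quota))
  if (quota[imax] < 0) stop("extent too small to place all classes")

  cls <- matrix(NA_integer_, n, n)
  idx <- function(i, j) (j - 1L) * n + i

  ## water: fill leftmost columns (partial last column from the top)
  nw <- quota[["water"]]
  if (nw > 0) {
    full_cols <- nw %/% n
    rem <- nw %% n
    if (full_cols > 0) cls[, seq_len(full_cols)] <- base_classes[["water"]]
    if (rem > 0) cls[seq_len(rem), full_cols + 1L] <- base_classes[["water"]]
  }

  land <- which(is.na(cls))
  ri <- (land - 1L) %% n + 1L
  ci <- (land - 1L) %/% n + 1L
  cx <- (n + 1) / 2
  cy <- if (length(ci) > 0) (min(ci) + n) / 2 else cx
  d <- sqrt((ri - cx)^2 + (ci - cy)^2) + stats::runif(length(land), 0, 2)

  ## forest: outermost land pixels
  nf <- quota[["forest"]]
  if (nf > 0) {
    ord <- order(d, decreasing = TRUE)
    take <- land[ord[seq_len(min(nf, length(land)))]]
    cls[take] <- base_classes[["forest"]]
  }

  urban <- which(is.na(cls))
  U <- length(urban)
  in_urban <- matrix(FALSE, n, n); in_urban[urban] <- TRUE

  ## roads: grid corridors over the urban area + one 3-cell highway band
  nr_ <- quota[["road_path"]]
  if (nr_ > 0 && U > 0) {
    f <- nr_ / U
    s <- max(4L, as.integer(round(2 / max(f, 1e-6))))
    off <- 1L + (blueprint$seed %% s)
    road <- matrix(FALSE, n, n)
    road[seq(off, n, by = s), ] <- TRUE
    road[, seq(off, n, by = s)] <- TRUE
    hw <- pmin(pmax(round(cx) + (-1:1), 1L), n)
    road[hw, ] <- TRUE
    sel <- which(road & in_urban)
    cls[sel] <- base_classes[["road_path"]]
  }

  ## helper: unassigned urban cells 4-adjacent to a road
  road_adjacent <- function() {
    rp <- cls == base_classes[["road_path"]]
    rp[is.na(rp)] <- FALSE
    adj <- matrix(FALSE, n, n)
    adj[-1, ] <- adj[-1, ] | rp[-n, ]
    adj[-n, ] <- adj[-n, ] | rp[-1, ]
    adj[, -1] <- adj[, -1] | rp[, -n]
    adj[, -n] <- adj[, -n] | rp[, -1]
    which(adj & is.na(cls) & in_urban)
  }

  place_near_roads <- function(code, k) {
    if (k <= 0) return(invisible())
    pool <- road_adjacent()
    take <- if (length(pool) > k) sample(pool, k) else pool
    cls[take] <<- code
    k <- k - length(take)
    if (k > 0) { # fall back to any unassigned urban cell
      pool <- which(is.na(cls) & in_urban)
      take <- if (length(pool) > k) sample(pool, k) else pool
      cls[take] <<- code
    }
  }

  place_near_roads(base_classes[["sidewalk"]], quota[["sidewalk"]])
  place_near_roads(base_classes[["traffic_island"]], quota[["traffic_island"]])

  ## buildings then other impervious: closest to centre first
  dmat <- matrix(Inf, n, n); dmat[land] <- d
  place_central <- function(code, k) {
    if (k <= 0) return(invisible())
    pool <- which(is.na(cls) & in_urban)
    ord <- order(dmat[pool])
    cls[pool[ord[seq_len(min(k, length(pool)))]]] <<- code
  }
  place_central(base_classes[["building"]], quota[["building"]])
  place_central(base_classes[["other_impervious"]], quota[["other_impervious"]])

  ## garden (or the largest remaining class) fills the rest
  rest <- which(is.na(cls))
  fill_code <- if (mix[["garden"]] > 0) base_classes[["garden"]] else
    base_classes[[names(which.max(mix))]]
  cls[rest] <- fill_code

  attr(cls, "res") <- blueprint$coarse_res_m
  cls
}

# per-class target densities of the fine masks
tree_density_by_class <- c(
  water = 0, forest = 0.88, garden = 0.45, building = 0.05,
  road_path = 0.04, sidewalk = 0.15, traffic_island = 0.30,
  other_impervious = 0.10
)
building_density_by_class <- c(
  water = 0, forest = 0, garden = 0.02, building = 0.88,
  road_path = 0, sidewalk = 0, traffic_island = 0,
  other_impervious = 0.10
)

# precomputed disk offsets (fine cells) for pseudo-crown placement
disk_offsets <- function(r) {
  g <- expand.grid(di = -r:r, dj = -r:r)
  g <- g[g$di^2 + g$dj^2 <= r^2 + 0.5, ]
  as.matrix(g)
}

#' Generate fine-resolution tree and building masks
#'
#' Builds two binary masks on the fine grid, statistically consistent with
#' the coarse LULC: buildings are rectangles covering most of each
#' `building` cell, trees are pseudo-disks (crown radius about 5 fine cells
#' for dense cover, smaller for sparse cover) placed with class-conditional
#' intensities. Disks are clipped to their coarse cell and trimmed so each
#' cell's realized tree fraction matches its (jittered) class target; tree
#' and building masks never overlap.
#'
#' @param lulc Coarse LULC raster from [make_lulc()].
#' @param blueprint The same [city_blueprint()].
#' @param tree_density,building_density Named per-class target cover
#'   fractions; defaults emulate a temperate European urban fabric.
#' @return List with binary integer matrices `tree` and `building` at fine
#'   resolution (attribute `res`).
#' @export
make_masks <- function(lulc, blueprint,
                       tree_density = tree_density_by_class,
                       building_density = building_density_by_class) {
  stopifnot(inherits(blueprint, "city_blueprint"))
  f <- blueprint$coarse_res_m %/% blueprint$fine_res_m
  n <- nrow(lulc)
  if (ncol(lulc) != n) stop("lulc must be square")
  nf <- n * f
  set.seed(blueprint$seed + 1L)

  cname <- names(base_classes)[match(lulc, base_classes)]
  p_tree <- tree_density[cname]
  p_bld <- building_density[cname]
  # per-cell jitter so refined tree bins vary within a class; classes with a
  # zero target (e.g. water) stay exactly empty
  jt <- stats::rnorm(length(p_tree), 0, 0.10)
  jb <- stats::rnorm(length(p_bld), 0, 0.04)
  p_tree <- ifelse(p_tree > 0, pmin(pmax(p_tree + jt, 0), 1), 0)
  p_bld <- ifelse(p_bld > 0, pmin(pmax(p_bld + jb, 0), 1), 0)

  tree <- matrix(0L, nf, nf)
  bld <- matrix(0L, nf, nf)
  cell_area <- f * f
  disks <- list(small = disk_offsets(max(2L, f %/% 5L)),
                large = disk_offsets(f %/% 2L))

  for (k in seq_along(cname)) {
    i0 <- ((k - 1L) %% n) * f     # 0-based top row of the block
    j0 <- ((k - 1L) %/% n) * f

    ## building rectangle(s)
    qb <- round(p_bld[k] * cell_area)
    if (qb > 0) {
      h <- min(f, max(1L, round(sqrt(qb))))
      w <- min(f, ceiling(qb / h))
      oi <- sample.int(f - h + 1L, 1L)
      oj <- sample.int(f - w + 1L, 1L)
      bi <- i0 + oi:(oi + h - 1L)
      bj <- j0 + oj:(oj + w - 1L)
      bld[bi, bj] <- 1L
    }

    ## tree disks, trimmed to the cell quota
    qt <- round(p_tree[k] * cell_area)
    if (qt == 0) next
    block_free <- cell_area - sum(bld[(i0 + 1L):(i0 + f), (j0 + 1L):(j0 + f)])
    qt <- min(qt, block_free)
    if (qt <= 0) next
    placed <- integer(0)
    got <- 0L
    it <- 0L
    while (got < qt && it < 20L) {
      it <- it + 1L
      dsk <- if (p_tree[k] >= 0.6) disks$large else disks$small
      ci <- sample.int(f, 1L); cj <- sample.int(f, 1L)
      di <- ci + dsk[, 1L]; dj <- cj + dsk[, 2L]
      keep <- di >= 1L & di <= f & dj >= 1L & dj <= f
      cells <- (j0 + dj[keep] - 1L) * nf + (i0 + di[keep])
      cells <- cells[bld[cells] == 0L & tree[cells] == 0L]
      if (got + length(cells) > qt)
        cells <- cells[sample.int(length(cells), qt - got)]
      tree[cells] <- 1L
      got <- got + length(cells)
    }
    if (got < qt) { # fill remainder with scattered cells
      blk <- as.vector(outer((i0 + 1L):(i0 + f), (j0 + seq_len(f) - 1L) * nf, `+`))
      free <- blk[tree[blk] == 0L & bld[blk] == 0L]
      if (length(free) > 0) {
        add <- free[sample.int(length(free), min(qt - got, length(free)))]
        tree[add] <- 1L
      }
    }
  }
  attr(tree, "res") <- blueprint$fine_res_m
  attr(bld, "res") <- blueprint$fine_res_m
  list(tree = tree, building = bld)
}

#' Generate the 100 m gridded population
#'
#' Distributes `pop_total` inhabitants over 100 m cells by a multinomial
#' draw weighted by each cell's count of `building` LULC pixels, so the
#' population concentrates where the buildings are (the dense core).
#'
#' @param lulc Coarse LULC raster from [make_lulc()].
#' @param pop_total Total inhabitants (non-negative integer).
#' @param seed Integer seed.
#' @param pop_res_m Population cell size in metres (default 100).
#' @return Integer matrix of person counts summing exactly to `pop_total`,
#'   with attribute `res`.
#' @export
make_population <- function(lulc, pop_total, seed = 0L, pop_res_m = 100) {
  res <- attr(lulc, "res")
  if (is.null(res)) res <- 10
  if (pop_res_m %% res != 0) stop("population resolution must be a multiple of the LULC resolution")
  k <- pop_res_m %/% res
  n <- nrow(lulc)
  if (n %% k != 0) stop("extent not divisible by the population resolution")
  np <- n %/% k
  bmat <- (lulc == base_classes[["building"]]) * 1
  w <- block_aggregate(bmat, k) * k * k   # building pixels per 100 m cell
  pop <- matrix(0L, np, np)
  if (pop_total > 0) {
    if (sum(w) == 0) stop("no building pixels: population cannot be placed")
    set.seed(seed)
    draw <- stats::rmultinom(1L, size = pop_total, prob = as.vector(w))
    pop[] <- as.integer(draw)
  }
  attr(pop, "res") <- pop_res_m
  pop
}

#' Generate a station temperature series at 21.00
#'
#' Emulates a summer network of temperature stations spanning an
#' urbanity gradient: each day has a rural base temperature with a seasonal
#' arc, and each station adds a share of that day's heat-island magnitude
#' according to its urbanity, plus measurement noise. The series always
#' contains at least one admissible reference day (minimum station
#' temperature above 20 degrees C).
#'
#' @param n_stations Number of stations (at least 2).
#' @param n_days Number of days.
#' @param seed Integer seed.
#' @param start Date of the first day.
#' @return Data frame with columns `date`, `station_id`, `temp_21h_c`.
#' @export
make_station_series <- function(n_stations = 8, n_days = 60, seed = 0L,
                                start = as.Date("2018-06-15")) {
  if (n_stations < 2) stop("need at least 2 stations")
  set.seed(seed)
  urbanity <- seq(0, 1, length.out = n_stations)
  days <- seq_len(n_days)
  base <- 16 + 7 * sin(pi * days / n_days) + stats::rnorm(n_days, 0, 1.2)
  uhi <- pmax(stats::rnorm(n_days, 4.5, 1.5), 0.2)
  tab <- expand.grid(day = days, station = seq_len(n_stations))
  tab$temp <- base[tab$day] + urbanity[tab$station] * uhi[tab$day] +
    stats::rnorm(nrow(tab), 0, 0.25)
  # guarantee an admissible reference day: lift all days if the best day's
  # coolest station does not clear 20 degrees C
  day_min <- tapply(tab$temp, tab$day, min)
  if (max(day_min) <= 20) tab$temp <- tab$temp + (20.6 - max(day_min))
  data.frame(date = start + tab$day - 1L,
             station_id = sprintf("S%02d", tab$station),
             temp_21h_c = tab$temp,
             stringsAsFactors = FALSE)
}

#' Generate every pipeline input for a synthetic city
#'
#' Convenience wrapper running [make_lulc()], [make_masks()],
#' [make_population()] and [make_station_series()] from one blueprint.
#'
#' @param blueprint A [city_blueprint()].
#' @return List with `lulc`, `tree_mask`, `building_mask`, `population`,
#'   `stations` and the `blueprint`.
#' @export
synth_city <- function(blueprint = city_blueprint()) {
  lulc <- make_lulc(blueprint)
  masks <- make_masks(lulc, blueprint)
  pop <- make_population(lulc, blueprint$pop_total, seed = blueprint$seed + 2L)
  stations <- make_station_series(seed = blueprint$seed + 3L)
  list(lulc = lulc, tree_mask = masks$tree, building_mask = masks$building,
       population = pop, stations = stations, blueprint = blueprint)
}
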
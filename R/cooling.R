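#' Climate and cooling-model parameters
#'
#' Bundles the scalar parameters of the urban cooling simulation. `t_ref`
#' and `uhi_max` are typically derived from a station series with
#' [select_reference_day()]; the defaults correspond to a hot summer
#' reference evening. The cooling-capacity weights, park cooling distance,
#' air-blending radius and minimum green-area size follow the defaults of
#' the widely used ecosystem-service cooling model this module
#' reimplements, and are configuration rather than constants.
#'
#' @param t_ref Rural reference air temperature at 21.00 (degrees C).
#' @param uhi_max Maximum urban heat island magnitude (degrees C).
#' @param et_max Maximum reference evapotranspiration over the extent
#'   (mm/day); if `NULL`, taken as the maximum of the supplied ET0 raster.
#' @param cc_weights Named weights (`shade`, `albedo`, `eti`) summing to 1.
#' @param d_cool Park cooling distance (m).
#' @param r_mix Air-blending radius (m).
#' @param green_area_min Minimum green patch area for the park effect (ha).
#' @return An object of class `climate_params`.
#' @export
climate_params <- function(t_ref = 20.60, uhi_max = 7.48, et_max = NULL,
                           cc_weights = c(shade = 0.6, albedo = 0.2,
                                          eti = 0.2),
                           d_cool = 100, r_mix = 500, green_area_min = 2) {
  if (uhi_max < 0) stop("uhi_max must be non-negative")
  if (any(cc_weights < 0) || abs(sum(cc_weights) - 1) > 1e-9)
    stop("cc_weights must be non-negative and sum to 1")
  if (d_cool <= 0 || r_mix <= 0) stop("d_cool and r_mix must be positive")
  if (!is.null(et_max) && et_max <= 0) stop("et_max must be positive")
  structure(list(t_ref = t_ref, uhi_max = uhi_max, et_max = et_max,
                 cc_weights = cc_weights, d_cool = d_cool, r_mix = r_mix,
                 green_area_min = green_area_min),
            class = "climate_params")
}

#' Hargreaves reference evapotranspiration
#'
#' `ET0 = 0.0023 * ra * (t_avg + 17.8) * sqrt(t_max - t_min)`, floored at
#' zero. Temperature-based; `ra` is the extraterrestrial radiation
#' expressed in mm/day of evaporation equivalent. Vectorised.
#'
#' @param t_min,t_avg,t_max Daily minimum / average / maximum air
#'   temperature (degrees C).
#' @param ra Extraterrestrial radiation (mm/day water equivalent).
#' @return Reference evapotranspiration (mm/day).
#' @export
hargreaves_et0 <- function(t_min, t_avg, t_max, ra) {
  if (any(t_min > t_max)) stop("t_min exceeds t_max: invalid day")
  pmax(0.0023 * ra * (t_avg + 17.8) * sqrt(t_max - t_min), 0)
}

#' Select the reference day from a station series
#'
#' Among days whose coolest station reads above `min_t_ref` at 21.00, picks
#' the day with the largest spread between the warmest and coolest station.
#' That spread is the heat-island magnitude `uhi_max`; the coolest station's
#' reading is the rural reference `t_ref`.
#'
#' @param stations Data frame with columns `date`, `station_id`,
#'   `temp_21h_c` (at least 2 stations).
#' @param min_t_ref Admissibility floor for `t_ref` (degrees C, strict).
#' @return List with `day`, `t_ref`, `uhi_max`.
#' @export
select_reference_day <- function(stations, min_t_ref = 20) {
  need <- c("date", "station_id", "temp_21h_c")
  if (!all(need %in% names(stations)))
    stop("station table must have columns: ", paste(need, collapse = ", "))
  if (length(unique(stations$station_id)) < 2)
    stop("need at least 2 stations")
  lo <- tapply(stations$temp_21h_c, stations$date, min)
  hi <- tapply(stations$temp_21h_c, stations$date, max)
  adm <- lo > min_t_ref
  if (!any(adm))
    stop("no admissible day: minimum station temperature never exceeds ",
         min_t_ref)
  spread <- hi - lo
  spread[!adm] <- -Inf
  i <- which.max(spread)
  list(day = names(lo)[i], t_ref = unname(lo[i]), uhi_max = unname(spread[i]))
}

#' Evapotranspiration index
#'
#' `ETI = kc * ET0 / et_max`, clipped to `[0, 1]`.
#'
#' @param kc Crop coefficient (>= 0).
#' @param et0 Reference evapotranspiration (mm/day).
#' @param et_max Maximum ET0 over the extent (mm/day, > 0).
#' @return Fraction(s) in `[0, 1]`.
#' @export
eti_index <- function(kc, et0, et_max) {
  if (et_max <= 0) stop("et_max must be positive")
  pmin(pmax(kc * et0 / et_max, 0), 1)
}

#' Cooling capacity
#'
#' Convex combination of the three cooling mechanisms:
#' `CC = w_shade * shade + w_albedo * albedo + w_eti * ETI`.
#'
#' @param shade,albedo,eti Fractions in `[0, 1]` (scalars or matrices).
#' @param weights Named weights (`shade`, `albedo`, `eti`) summing to 1.
#' @return Cooling capacity in `[0, 1]`, same shape as the inputs.
#' @export
cooling_capacity <- function(shade, albedo, eti,
                             weights = c(shade = 0.6, albedo = 0.2,
                                         eti = 0.2)) {
  if (abs(sum(weights) - 1) > 1e-9)
    stop("cooling-capacity weights must sum to 1")
  weights[["shade"]] * shade + weights[["albedo"]] * albedo +
    weights[["eti"]] * eti
}

#' Precompute the park-effect context
#'
#' Identifies 8-connected green patches of at least `green_area_min`
#' hectares and the exponential-decay kernel offsets within the cooling
#' distance. The context only depends on the green mask and the geometry,
#' so it can be reused across scenarios whose green classes do not change.
#'
#' @param green_mask Logical matrix: green-area-flagged pixels.
#' @param res Cell size (m).
#' @param params A [climate_params()].
#' @return List used by [heat_mitigation()].
#' @export
park_context <- function(green_mask, res, params) {
  lab <- .label_components(green_mask, 8L)
  G <- matrix(FALSE, nrow(green_mask), ncol(green_mask))
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    min_cells <- params$green_area_min * 1e4 / (res * res)
    big <- which(sizes >= min_cells)
    G <- matrix(lab %in% big, nrow(green_mask))
  }
  r_px <- floor(params$d_cool / res)
  off <- expand.grid(di = -r_px:r_px, dj = -r_px:r_px)
  d <- sqrt(off$di^2 + off$dj^2) * res
  keep <- d <= params$d_cool
  ctx <- list(G = G,
              offsets = cbind(off$di[keep], off$dj[keep]),
              w = exp(-d[keep] / params$d_cool))
  den <- matrix(0, nrow(G), ncol(G))
  if (any(G))
    for (k in seq_along(ctx$w))
      den <- shift_accumulate(den, G * 1, ctx$offsets[k, 1L],
                              ctx$offsets[k, 2L], ctx$w[k])
  ctx$den <- den
  ctx
}

# acc(i,j) += w * x(i+di, j+dj) over the valid overlap
shift_accumulate <- function(acc, x, di, dj, w) {
  nr <- nrow(x); nc <- ncol(x)
  i1 <- max(1, 1 - di); i2 <- min(nr, nr - di)
  j1 <- max(1, 1 - dj); j2 <- min(nc, nc - dj)
  if (i1 > i2 || j1 > j2) return(acc)
  acc[i1:i2, j1:j2] <- acc[i1:i2, j1:j2] +
    w * x[(i1 + di):(i2 + di), (j1 + dj):(j2 + dj)]
  acc
}

#' Heat-mitigation index
#'
#' Starts from the cooling capacity and adds the cooling influence of
#' large green areas: where a green patch of at least `green_area_min`
#' hectares lies within the cooling distance `d_cool`, the index is raised
#' to the distance-weighted mean of the green pixels' cooling capacity
#' (weights `exp(-d / d_cool)`), if that exceeds the pixel's own CC.
#'
#' @param cc Cooling-capacity matrix in `[0, 1]`.
#' @param green_mask Logical matrix of green-area-flagged pixels (ignored
#'   if `park` is supplied).
#' @param res Cell size (m).
#' @param params A [climate_params()].
#' @param park Optional precomputed [park_context()].
#' @return Heat-mitigation matrix in `[0, 1]`.
#' @export
heat_mitigation <- function(cc, green_mask = NULL, res = 10,
                            params = climate_params(), park = NULL) {
  if (is.null(park)) {
    if (is.null(green_mask)) stop("either green_mask or park must be given")
    park <- park_context(green_mask, res, params)
  }
  G <- park$G
  if (!any(G)) return(cc)
  num <- matrix(0, nrow(cc), ncol(cc))
  gcc <- cc * G
  for (k in seq_along(park$w))
    num <- shift_accumulate(num, gcc, park$offsets[k, 1L],
                            park$offsets[k, 2L], park$w[k])
  hm <- cc
  hit <- park$den > 0
  hm[hit] <- pmax(cc[hit], num[hit] / park$den[hit])
  pmin(pmax(hm, 0), 1)
}

# 1-D Gaussian blending operator with row renormalization (matrix form)
gaussian_operator <- function(n, sigma_px) {
  radius <- ceiling(3 * sigma_px)
  K <- matrix(0, n, n)
  for (o in -radius:radius) {
    lo <- max(1, 1 - o); hi <- min(n, n - o)
    if (lo > hi) next
    K[cbind(lo:hi, (lo:hi) + o)] <- exp(-(o / sigma_px)^2 / 2)
  }
  K / rowSums(K)
}

#' Air temperature from the heat-mitigation index
#'
#' The unmixed temperature is `t_ref + (1 - HM) * uhi_max`; air mixing is a
#' Gaussian moving average with standard deviation `r_mix / 3`, truncated
#' at three standard deviations and renormalized at the raster border. The
#' blending is a convex average, so temperatures remain within
#' `[t_ref, t_ref + uhi_max]`.
#'
#' @param hm Heat-mitigation matrix in `[0, 1]`.
#' @param params A [climate_params()].
#' @param res Cell size (m).
#' @return Object of class `temperature_field`: list with `hm`, `t_air`,
#'   `t_bar` (mean over pixels), `t_ref`, `uhi_max`, `res`.
#' @export
temperature_map <- function(hm, params = climate_params(), res = 10) {
  if (any(hm < -1e-12 | hm > 1 + 1e-12)) stop("hm must lie in [0, 1]")
  t_nomix <- params$t_ref + (1 - hm) * params$uhi_max
  sigma_px <- (params$r_mix / 3) / res
  Kr <- gaussian_operator(nrow(hm), sigma_px)
  Kc <- if (ncol(hm) == nrow(hm)) Kr else gaussian_operator(ncol(hm), sigma_px)
  t_air <- Kr %*% t_nomix %*% t(Kc)
  structure(list(hm = hm, t_air = t_air, t_bar = mean(t_air),
                 t_ref = params$t_ref, uhi_max = params$uhi_max, res = res),
            class = "temperature_field")
}

#' @export
print.temperature_field <- function(x, ...) {
  cat(sprintf(
    "<temperature_field> %d x %d at %g m: mean %.3f, range [%.3f, %.3f] degC\n",
    nrow(x$t_air), ncol(x$t_air), x$res, x$t_bar, min(x$t_air), max(x$t_air)))
  invisible(x)
}

# bilinear resize of a matrix to nr x nc (cell-centre alignment)
bilinear_resize <- function(x, nr, nc) {
  sr <- nrow(x) / nr; sc <- ncol(x) / nc
  ri <- pmin(pmax((seq_len(nr) - 0.5) * sr + 0.5, 1), nrow(x))
  ci <- pmin(pmax((seq_len(nc) - 0.5) * sc + 0.5, 1), ncol(x))
  r0 <- pmin(floor(ri), nrow(x) - 1L); fr <- ri - r0
  c0 <- pmin(floor(ci), ncol(x) - 1L); fc <- ci - c0
  a <- x[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
    x[r0 + 1, c0, drop = FALSE] * outer(fr, 1 - fc) +
    x[r0, c0 + 1, drop = FALSE] * outer(1 - fr, fc) +
    x[r0 + 1, c0 + 1, drop = FALSE] * outer(fr, fc)
  a
}

#' Simulate air temperature for a refined LULC grid
#'
#' Composes the full cooling chain: per-class lookup of shade, albedo, crop
#' coefficient and green-area flag from the biophysical table;
#' evapotranspiration index; cooling capacity; park-effect heat
#' mitigation; Gaussian air mixing; temperature mapping.
#'
#' @param refined A [refined_lulc()] object.
#' @param biophys A [biophysical_table()] covering every code in the grid.
#' @param et0 Reference evapotranspiration: a scalar, a matrix matching the
#'   grid, or a coarser matrix (bilinearly resampled to the grid).
#' @param params A [climate_params()]; if `et_max` is `NULL` it is taken
#'   as `max(et0)`.
#' @param park Optional precomputed [park_context()] (reusable across
#'   scenarios because the green-area mask does not change under canopy
#'   transformation).
#' @return A `temperature_field` (see [temperature_map()]).
#' @export
simulate_temperature <- function(refined, biophys, et0 = 5,
                                 params = climate_params(), park = NULL) {
  codes <- refined$codes
  m <- match(codes, biophys$code)
  if (anyNA(m))
    stop("codes missing from the biophysical table: ",
         paste(unique(codes[is.na(m)]), collapse = ", "))
  shade <- matrix(biophys$shade[m], nrow(codes))
  albedo <- matrix(biophys$albedo[m], nrow(codes))
  kc <- matrix(biophys$kc[m], nrow(codes))
  green <- matrix(biophys$green_area[m], nrow(codes))

  if (length(et0) == 1) {
    et0m <- matrix(et0, nrow(codes), ncol(codes))
  } else if (all(dim(et0) == dim(codes))) {
    et0m <- et0
  } else {
    et0m <- bilinear_resize(et0, nrow(codes), ncol(codes))
  }
  et_max <- if (is.null(params$et_max)) max(et0m) else params$et_max

  eti <- eti_index(kc, et0m, et_max)
  cc <- cooling_capacity(shade, albedo, eti, params$cc_weights)
  hm <- heat_mitigation(cc, green_mask = green, res = refined$res,
                        params = params, park = park)
  temperature_map(hm, params, res = refined$res)
}
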
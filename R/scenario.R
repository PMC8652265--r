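#' Scenario configuration
#'
#' @param proportion Fraction of candidate pixels to transform, in `(0, 1]`.
#' @param strategy Allocation strategy: `"random"` (uniform sampling),
#'   `"cluster"` (prefer candidates with many high-canopy Moore neighbours)
#'   or `"scatter"` (prefer candidates with few).
#' @param run_seed Integer seed making the run fully reproducible.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(proportion, strategy = c("random", "cluster",
                                                     "scatter"),
                            run_seed = 0L) {
  strategy <- match.arg(strategy)
  if (!(proportion > 0 && proportion <= 1))
    stop("proportion must lie in (0, 1]")
  structure(list(proportion = proportion, strategy = strategy,
                 run_seed = as.integer(run_seed)),
            class = "scenario_config")
}

#' Find candidate pixels for canopy transformation
#'
#' A pixel is a candidate iff (a) its base class is one of
#' [candidate_classes] (building, road/path, sidewalk, traffic island,
#' other impervious, garden); (b) its building-cover bin is 0 (building
#' cover under 25%, leaving room for a tree crown); (c) if it is a
#' road/path pixel, at least one of its 8 Moore neighbours has a different
#' base class (excluding mid-road pixels such as highways); and (d) its
#' tree-cover bin is below the top bin, so transformation actually changes
#' it.
#'
#' @param refined A [refined_lulc()] object.
#' @return Object of class `candidate_set`: data frame of `row`, `col`
#'   (column-major order) with attribute `total_count` and `dim`.
#' @export
find_candidates <- function(refined) {
  base <- refined$codes %/% 100L
  tb <- tree_bin_of(refined)
  bb <- building_bin_of(refined)
  cand_codes <- base_classes[candidate_classes]
  ok <- matrix(base %in% cand_codes, nrow = nrow(base)) &
    (bb == 0L) & (tb < 3L)

  ## road-adjacency rule: any in-bounds Moore neighbour of different class
  road <- base == base_classes[["road_path"]]
  if (any(road & ok)) {
    diff_nb <- matrix(FALSE, nrow(base), ncol(base))
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      sh <- shift_matrix(base, di, dj)
      cmp <- !is.na(sh) & sh != base
      diff_nb <- diff_nb | cmp
    }
    ok <- ok & (!road | diff_nb)
  }

  w <- which(ok)
  out <- data.frame(row = (w - 1L) %% nrow(base) + 1L,
                    col = (w - 1L) %/% nrow(base) + 1L)
  structure(out, total_count = nrow(out), dim_grid = dim(base),
            class = c("candidate_set", "data.frame"))
}

# shift a matrix by (di, dj); vacated cells become NA
shift_matrix <- function(x, di, dj) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(NA, nr, nc)
  si <- max(1, 1 + di):min(nr, nr + di)
  sj <- max(1, 1 + dj):min(nc, nc + dj)
  out[si, sj] <- x[si - di, sj - dj, drop = FALSE]
  out
}

# half-up rounding, documented so selection counts are exactly reproducible
round_half_up <- function(x) floor(x + 0.5)

#' Seeded allocation order of the candidate pixels
#'
#' Produces the complete ordering in which a strategy would transform the
#' candidates; a scenario at proportion p is the first
#' `round(p * total_count)` entries (so scenarios at increasing proportions
#' are nested for a fixed strategy and seed). `random` is a uniform
#' permutation; `cluster` and `scatter` greedily pick the candidate with
#' the largest / smallest number of high-canopy pixels in its Moore
#' neighbourhood, ties broken uniformly at random. With `dynamic = TRUE`
#' (default) a picked pixel immediately counts as high canopy for its
#' neighbours' scores.
#'
#' @param candidates A [find_candidates()] result.
#' @param refined The matching [refined_lulc()] object.
#' @param strategy One of `"random"`, `"cluster"`, `"scatter"`.
#' @param seed Integer seed.
#' @param dynamic Recompute neighbour counts as pixels are transformed
#'   (static counts are available for comparison).
#' @return Integer vector: row indices into `candidates` in pick order.
#' @export
candidate_order <- function(candidates, refined, strategy, seed,
                            dynamic = TRUE) {
  n <- attr(candidates, "total_count")
  set.seed(seed)
  if (strategy == "random") return(sample.int(n))
  idx0 <- (candidates$col - 1L) * nrow(refined$codes) + candidates$row - 1L
  ord0 <- .greedy_order(as.integer(idx0), is_high_canopy(refined),
                        maximize = (strategy == "cluster"),
                        dynamic_counts = dynamic)
  ord0 + 1L
}

#' Sample the pixels of one greening scenario
#'
#' Selects exactly `round(p * total_count)` candidate pixels (half-up
#' rounding) according to the configuration's strategy. At `p = 1` the full
#' candidate set is returned, identically for every strategy and seed.
#'
#' @param candidates A [find_candidates()] result.
#' @param refined The matching [refined_lulc()] object.
#' @param config A [scenario_config()].
#' @param dynamic Passed to [candidate_order()].
#' @return Data frame of `row`, `col` of the selected pixels.
#' @export
sample_pixels <- function(candidates, refined, config, dynamic = TRUE) {
  n <- attr(candidates, "total_count")
  if (n == 0) stop("candidate set is empty")
  k <- round_half_up(config$proportion * n)
  if (k == 0) {
    warning("proportion rounds to zero pixels; returning an empty set")
    return(candidates[integer(0), , drop = FALSE])
  }
  if (config$proportion == 1)
    return(as.data.frame(candidates)[, c("row", "col")])
  ord <- candidate_order(candidates, refined, config$strategy,
                         config$run_seed, dynamic = dynamic)
  as.data.frame(candidates)[ord[seq_len(k)], c("row", "col")]
}

#' Apply a greening scenario to a refined grid
#'
#' The selected pixels move to the refined code with the same base class
#' and building bin but the highest tree-cover bin; all other pixels are
#' unchanged. Idempotent.
#'
#' @param refined A [refined_lulc()] object.
#' @param pixels Data frame with `row`, `col` columns (within the grid).
#' @return A new [refined_lulc()] object.
#' @export
apply_scenario <- function(refined, pixels) {
  codes <- refined$codes
  if (nrow(pixels) > 0) {
    if (any(pixels$row < 1 | pixels$row > nrow(codes) |
            pixels$col < 1 | pixels$col > ncol(codes)))
      stop("pixel outside the grid extent")
    w <- (pixels$col - 1L) * nrow(codes) + pixels$row
    tb <- (codes[w] %/% 10L) %% 10L
    codes[w] <- codes[w] + (3L - tb) * 10L
  }
  refined_lulc(codes, res = refined$res)
}

#' Tally transformed pixels by their original base class
#'
#' @param pixels Data frame with `row`, `col` columns.
#' @param refined The pre-transformation [refined_lulc()] object.
#' @return Named integer vector over all base classes (zeros included);
#'   sums to `nrow(pixels)`.
#' @export
tally_by_class <- function(pixels, refined) {
  out <- stats::setNames(integer(length(base_classes)), names(base_classes))
  if (nrow(pixels) > 0) {
    w <- (pixels$col - 1L) * nrow(refined$codes) + pixels$row
    b <- refined$codes[w] %/% 100L
    tab <- table(names(base_classes)[match(b, base_classes)])
    out[names(tab)] <- as.integer(tab)
  }
  out
}
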
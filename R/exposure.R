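#' Aggregate air temperature to population cells
#'
#' Each population cell's temperature is the arithmetic mean (default) or
#' the maximum of the temperature pixels it covers. The whole-cell census
#' resolution means exposure is attributed per cell, so the aggregation
#' rule is the only free choice here.
#'
#' @param t_air Temperature matrix at the fine (LULC) resolution.
#' @param factor Integer ratio of population to temperature resolution
#'   (e.g. 10 for 100 m cells over a 10 m grid).
#' @param method `"mean"` (default) or `"max"`.
#' @return Temperature matrix at population resolution.
#' @export
cell_temperature <- function(t_air, factor, method = c("mean", "max")) {
  method <- match.arg(method)
  factor <- as.integer(factor)
  if (nrow(t_air) %% factor != 0 || ncol(t_air) %% factor != 0)
    stop("temperature grid does not tile into population cells")
  if (method == "mean") return(block_aggregate(t_air, factor))
  nr <- nrow(t_air) %/% factor
  nc <- ncol(t_air) %/% factor
  out <- matrix(-Inf, nr, nc)
  for (di in seq_len(factor)) for (dj in seq_len(factor)) {
    sub <- t_air[seq(di, nrow(t_air), by = factor),
                 seq(dj, ncol(t_air), by = factor), drop = FALSE]
    out <- pmax(out, sub)
  }
  out
}

#' Population exposure above temperature thresholds
#'
#' For each threshold t, the exposed count is the population of cells whose
#' temperature is strictly higher than t.
#'
#' @param cell_temp Per-cell temperature matrix (from
#'   [cell_temperature()]).
#' @param population Per-cell population matrix, same shape.
#' @param thresholds Sorted temperature thresholds (degrees C).
#' @return Data frame with `threshold_c`, `exposed_count`,
#'   `exposed_share_pct`; counts are non-increasing in the threshold.
#' @export
exposure_table <- function(cell_temp, population, thresholds = 21:26) {
  if (!all(dim(cell_temp) == dim(population)))
    stop("temperature and population grids do not match")
  if (is.unsorted(thresholds)) stop("thresholds must be sorted")
  total <- sum(population)
  counts <- vapply(thresholds,
                   function(t) sum(population[cell_temp > t]), numeric(1))
  data.frame(threshold_c = thresholds,
             exposed_count = counts,
             exposed_share_pct = if (total > 0) 100 * counts / total else
               rep(0, length(counts)))
}
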
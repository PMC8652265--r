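#' Experiment design
#'
#' The full factorial of transformation proportions, allocation strategies
#' and stochastic runs, optionally completed by the single deterministic
#' scenario that transforms every candidate pixel. The default design has
#' 7 proportions x 3 strategies x 10 runs + 1 = 211 scenarios.
#'
#' @param proportions Proportions of candidate pixels to transform.
#' @param strategies Subset of `c("random", "cluster", "scatter")`.
#' @param runs_per_config Stochastic runs per (proportion, strategy).
#' @param include_full Add the deterministic 100% scenario.
#' @param master_seed Integer seed from which every run seed is derived.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(proportions = seq(0.125, 0.875, by = 0.125),
                              strategies = c("random", "cluster", "scatter"),
                              runs_per_config = 10,
                              include_full = TRUE,
                              master_seed = 42L) {
  stopifnot(all(proportions > 0 & proportions < 1),
            all(strategies %in% c("random", "cluster", "scatter")),
            runs_per_config >= 1)
  structure(list(proportions = proportions, strategies = strategies,
                 runs_per_config = as.integer(runs_per_config),
                 include_full = isTRUE(include_full),
                 master_seed = as.integer(master_seed)),
            class = "experiment_design")
}

#' Enumerate the scenarios of a design
#'
#' @param design An [experiment_design()].
#' @return Data frame with one row per scenario: `scenario_id`,
#'   `proportion`, `strategy`, `run`, `seed`. The full scenario (if any)
#'   has strategy `"full"`, run 0.
#' @export
design_configs <- function(design) {
  grid <- expand.grid(run = seq_len(design$runs_per_config),
                      proportion = design$proportions,
                      strategy = design$strategies,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("proportion", "strategy", "run")]
  if (design$include_full)
    grid <- rbind(grid, data.frame(proportion = 1, strategy = "full",
                                   run = 0L))
  grid$seed <- run_seed(design$master_seed, grid$strategy, grid$run)
  grid$scenario_id <- seq_len(nrow(grid))
  grid[, c("scenario_id", "proportion", "strategy", "run", "seed")]
}

# Per-run seed derived from (master seed, strategy, run) only: the
# candidate ordering of a run is shared by all proportions, which makes
# scenarios at increasing proportions nested truncations of one sequence.
run_seed <- function(master_seed, strategy, run) {
  si <- match(strategy, c("random", "cluster", "scatter", "full"))
  as.integer((as.numeric(master_seed) * 1000003 + si * 65537 + run * 101) %%
               2147483647)
}

#' Number of scenarios in a design
#'
#' @param design An [experiment_design()].
#' @return Integer scenario count.
#' @export
n_scenarios <- function(design) {
  length(design$proportions) * length(design$strategies) *
    design$runs_per_config + as.integer(design$include_full)
}

#' Run the full greening experiment
#'
#' Executes every scenario of the design on one set of inputs: finds the
#' candidate pixels once, computes each run's candidate ordering, truncates
#' it at each proportion, applies the transformation, simulates the
#' temperature field, and records landscape metrics, population exposure
#' and per-class transformation tallies. The whole experiment is a pure
#' function of (inputs, design).
#'
#' @param refined Baseline [refined_lulc()] grid.
#' @param base_table Per-base-class biophysical coefficients (from
#'   [base_biophysical()]); expanded internally to every refined code
#'   reachable under transformation.
#' @param population Population matrix (e.g. from [make_population()]).
#' @param params A [climate_params()].
#' @param design An [experiment_design()].
#' @param et0 Reference evapotranspiration passed to
#'   [simulate_temperature()].
#' @param thresholds Exposure thresholds (degrees C).
#' @param exposure_method Aggregation of pixel temperatures to population
#'   cells, `"mean"` or `"max"`.
#' @return Object of class `greening_experiment`: list with `results` (one
#'   row per scenario: configuration, mean/max temperature, maximum heat
#'   mitigation, the four landscape metrics, per-class tallies), `exposure`
#'   (long table over thresholds), `baseline` (scenario-0 temperature
#'   field and metrics), `maps` (per-proportion aggregate rasters: mean
#'   temperature, mean heat mitigation, modal LULC), `candidates` and
#'   `design`.
#' @export
run_experiment <- function(refined, base_table = base_biophysical(),
                           population = NULL,
                           params = climate_params(),
                           design = experiment_design(),
                           et0 = 5, thresholds = 21:26,
                           exposure_method = "mean") {
  candidates <- find_candidates(refined)
  n_cand <- attr(candidates, "total_count")
  if (n_cand == 0) stop("no candidate pixels in the refined grid")
  if (is.null(population)) stop("a population raster is required")
  res <- refined$res
  pop_res <- attr(population, "res")
  if (is.null(pop_res)) pop_res <- 100
  agg <- pop_res %/% res

  biophys <- biophysical_table(refined, base_table)

  green <- matrix(biophys$green_area[match(refined$codes, biophys$code)],
                  nrow(refined$codes))
  park <- park_context(green, res, params)

  baseline_tf <- simulate_temperature(refined, biophys, et0, params, park)
  baseline_metrics <- landscape_metrics(refined)
  baseline_exposure <- exposure_table(
    cell_temperature(baseline_tf$t_air, agg, exposure_method),
    population, thresholds)

  configs <- design_configs(design)
  cand_idx <- (candidates$col - 1L) * nrow(refined$codes) + candidates$row

  # per (strategy, run) candidate orderings, truncated per proportion
  orders <- new.env(parent = emptyenv())
  get_order <- function(strategy, run) {
    key <- paste(strategy, run)
    if (!is.null(orders[[key]])) return(orders[[key]])
    sd <- run_seed(design$master_seed, strategy, run)
    o <- candidate_order(candidates, refined, strategy, sd)
    orders[[key]] <- o
    o
  }

  # aggregate-map accumulators per proportion (plus the full scenario)
  props <- sort(unique(configs$proportion))
  acc <- lapply(props, function(p)
    list(t_sum = matrix(0, nrow(refined$codes), ncol(refined$codes)),
         hm_sum = matrix(0, nrow(refined$codes), ncol(refined$codes)),
         transformed_runs = matrix(0L, nrow(refined$codes),
                                   ncol(refined$codes)),
         n = 0L))
  names(acc) <- as.character(props)

  rows <- vector("list", nrow(configs))
  expo <- vector("list", nrow(configs))
  for (i in seq_len(nrow(configs))) {
    cf <- configs[i, ]
    k <- round_half_up(cf$proportion * n_cand)
    if (cf$strategy == "full") {
      sel <- seq_len(n_cand)
    } else {
      sel <- get_order(cf$strategy, cf$run)[seq_len(k)]
    }
    pixels <- as.data.frame(candidates)[sel, c("row", "col")]
    scn <- apply_scenario(refined, pixels)
    tf <- simulate_temperature(scn, biophys, et0, params, park)
    met <- landscape_metrics(scn)
    ex <- exposure_table(cell_temperature(tf$t_air, agg, exposure_method),
                         population, thresholds)
    tly <- tally_by_class(pixels, refined)

    rows[[i]] <- data.frame(
      cf,
      n_transformed = nrow(pixels),
      t_bar = tf$t_bar,
      t_min = min(tf$t_air),
      t_max = max(tf$t_air),
      max_heat_mitigation = max(baseline_tf$t_air - tf$t_air),
      met,
      as.list(stats::setNames(as.integer(tly),
                              paste0("n_", names(tly)))),
      stringsAsFactors = FALSE)
    expo[[i]] <- data.frame(scenario_id = cf$scenario_id,
                            proportion = cf$proportion,
                            strategy = cf$strategy, run = cf$run, ex,
                            stringsAsFactors = FALSE)

    a <- acc[[as.character(cf$proportion)]]
    a$t_sum <- a$t_sum + tf$t_air
    a$hm_sum <- a$hm_sum + tf$hm
    w <- (pixels$col - 1L) * nrow(refined$codes) + pixels$row
    a$transformed_runs[w] <- a$transformed_runs[w] + 1L
    a$n <- a$n + 1L
    acc[[as.character(cf$proportion)]] <- a
  }

  maps <- lapply(acc, function(a) {
    # a pixel has only two possible codes across runs (original or
    # top tree bin), so the modal LULC is "transformed in most runs"
    mode_codes <- refined$codes
    hit <- a$transformed_runs > a$n / 2
    tb <- (mode_codes %/% 10L) %% 10L
    mode_codes[hit] <- mode_codes[hit] + (3L - tb[hit]) * 10L
    list(t_air_mean = a$t_sum / a$n, hm_mean = a$hm_sum / a$n,
         lulc_mode = mode_codes, n_runs = a$n)
  })

  structure(list(results = do.call(rbind, rows),
                 exposure = do.call(rbind, expo),
                 baseline = list(temperature = baseline_tf,
                                 metrics = baseline_metrics,
                                 exposure = baseline_exposure),
                 maps = maps,
                 candidates = candidates,
                 design = design,
                 params = params),
            class = "greening_experiment")
}

#' @export
print.greening_experiment <- function(x, ...) {
  cat(sprintf("<greening_experiment> %d scenarios, %d candidate pixels\n",
              nrow(x$results), attr(x$candidates, "total_count")))
  cat(sprintf("mean T over scenarios: %.3f to %.3f degC\n",
              min(x$results$t_bar), max(x$results$t_bar)))
  invisible(x)
}

#' Mean and 95% confidence interval of per-run values
#'
#' Student-t interval: mean +/- t(0.975, n-1) * SE.
#'
#' @param values Numeric vector of per-run values.
#' @param level Confidence level (default 0.95).
#' @return Named vector `mean`, `lower`, `upper`; the interval is `NA`
#'   when fewer than 2 values are given.
#' @export
confidence_interval <- function(values, level = 0.95) {
  n <- length(values)
  m <- mean(values)
  if (n < 2) return(c(mean = m, lower = NA_real_, upper = NA_real_))
  se <- stats::sd(values) / sqrt(n)
  hw <- stats::qt(1 - (1 - level) / 2, df = n - 1) * se
  c(mean = m, lower = m - hw, upper = m + hw)
}

#' Contrast a quantity between allocation strategies
#'
#' Per proportion, the difference of run means between the random strategy
#' and each other strategy (random - scatter, random - cluster), with 95%
#' confidence intervals (Welch standard errors).
#'
#' @param experiment A [run_experiment()] result, or its `results` data
#'   frame.
#' @param quantity Column name to contrast (e.g. `"t_bar"`, `"pland"`,
#'   `"n_garden"`).
#' @param level Confidence level.
#' @return Data frame: `proportion`, `contrast`, `estimate`, `lower`,
#'   `upper`.
#' @export
strategy_contrast <- function(experiment, quantity = "t_bar", level = 0.95) {
  res <- if (inherits(experiment, "greening_experiment"))
    experiment$results else experiment
  res <- res[res$strategy != "full", ]
  need <- c("random", "cluster", "scatter")
  if (!all(need %in% res$strategy))
    stop("contrast requires matched configurations for all of: ",
         paste(need, collapse = ", "))
  if (!quantity %in% names(res)) stop("unknown quantity: ", quantity)
  out <- list()
  for (p in sort(unique(res$proportion))) {
    vr <- res[res$proportion == p & res$strategy == "random", quantity]
    for (other in c("scatter", "cluster")) {
      vo <- res[res$proportion == p & res$strategy == other, quantity]
      est <- mean(vr) - mean(vo)
      se <- sqrt(stats::var(vr) / length(vr) + stats::var(vo) / length(vo))
      df <- if (se > 0) se^4 / ((stats::var(vr) / length(vr))^2 /
                                  (length(vr) - 1) +
                                  (stats::var(vo) / length(vo))^2 /
                                  (length(vo) - 1)) else Inf
      hw <- if (se > 0) stats::qt(1 - (1 - level) / 2, df) * se else 0
      out[[length(out) + 1L]] <- data.frame(
        proportion = p, contrast = paste0("random_minus_", other),
        estimate = est, lower = est - hw, upper = est + hw,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
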
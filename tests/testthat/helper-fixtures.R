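# Shared fixtures, generated once per test session. The "small" city keeps
# unit tests fast; the default-scale city and its full 211-scenario
# experiment back the landscape-scale checks.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- make()
  .fixtures[[name]]
}

small_city <- function() fixture("small_city", function() {
  synth_city(city_blueprint(side_m = 500, pop_total = 2000, seed = 3))
})

small_refined <- function() fixture("small_refined", function() {
  city <- small_city()
  refine_lulc(city$lulc,
              cover_fractions(city$tree_mask, 10),
              cover_fractions(city$building_mask, 10))
})

default_city <- function() fixture("default_city", function() {
  synth_city(city_blueprint())
})

default_refined <- function() fixture("default_refined", function() {
  city <- default_city()
  refine_lulc(city$lulc,
              cover_fractions(city$tree_mask, 10),
              cover_fractions(city$building_mask, 10))
})

default_experiment <- function() fixture("default_experiment", function() {
  run_experiment(default_refined(),
                 population = default_city()$population,
                 design = experiment_design(master_seed = 42),
                 et0 = 5)
})

# a hand-built refined grid: garden everywhere, a block of high canopy in
# the north-west corner, roads in given columns
toy_refined <- function(n = 8, high = NULL, road_cols = integer(0)) {
  base <- matrix(base_classes[["garden"]], n, n)
  base[, road_cols] <- base_classes[["road_path"]]
  tfrac <- matrix(0.3, n, n)
  if (!is.null(high)) tfrac[high] <- 0.8
  refine_lulc(base, tfrac, matrix(0, n, n), res = 10)
}
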
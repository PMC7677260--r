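# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small noisy scenario (2 young + 2 old trees, 4 days)
smoke_scenario <- function() {
  fixture("smoke", function() simulate_scenario(
    scenario_config(n_young = 2, n_old = 2, n_days = 4, seed = 11)))
}

# noise-free scenario with grid-multiple lags: residuals at truth vanish
noisefree_scenario <- function() {
  fixture("noisefree", function() {
    cfg <- scenario_config(n_young = 2, n_old = 2, n_days = 9, seed = 21)
    truth <- default_truth(cfg)
    meteo <- gen_meteo(cfg)
    trees <- gen_trees(cfg, truth)
    trees$chi <- pmin(pmax(round(trees$chi / 10) * 10, 10), 180)
    data <- gen_observed_sapflow(trees, meteo, truth, cfg, noise = FALSE)
    list(data = data, truth = truth_vector(trees, truth), trees = trees,
         meteo = meteo, cfg = cfg)
  })
}

# published tree inventory joined with the published posterior modes
published_tables <- function() {
  info <- pine_tree_info()
  maps <- pine_map_estimates()
  merge(info, maps$trees, by = "tree_id", sort = FALSE)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}
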
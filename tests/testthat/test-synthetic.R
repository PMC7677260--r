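test_that("generated drivers have the designed diurnal structure", {
  cfg <- scenario_config(n_young = 1, n_old = 1, n_days = 6, seed = 1)
  m <- gen_meteo(cfg)
  h <- (as.numeric(m$timestamp) / 3600) %% 24
  expect_true(all(m$I[h > 22.01 | h < 4.01] == 0))
  expect_gt(sum(m$D == 0), 0)  # pre-dawn saturation rows exercise the filter
  day <- m$I > 0
  r <- cor(m$D[day], m$I[day])
  expect_gte(r, 0.3); expect_lte(r, 0.8)
  expect_true(all(m$RH_pct >= 0 & m$RH_pct <= 100))
  expect_true(all(m$D >= 0))
  # VPD and D consistent under the ideal-gas conversion at every row
  expect_equal(m$D, vpd_molar(m$VPD_pa, m$T_C), tolerance = 1e-12)
})

test_that("generator outputs are bit-reproducible given the seed", {
  cfg <- scenario_config(n_young = 2, n_old = 2, n_days = 2, seed = 17)
  a <- simulate_scenario(cfg)
  b <- simulate_scenario(cfg)
  expect_identical(a$meteo, b$meteo)
  expect_identical(a$trees, b$trees)
  expect_identical(a$truth, b$truth)
  expect_identical(lapply(a$data, function(d) d$full),
                   lapply(b$data, function(d) d$full))
})

test_that("tree-level truths respect their boxes and height relations", {
  cfg <- scenario_config(seed = 2)
  tr <- gen_trees(cfg, default_truth(cfg))
  y <- tr$age_group == "young"
  expect_true(all(tr$height_m[y] >= 16 & tr$height_m[y] <= 21))
  expect_true(all(tr$height_m[!y] >= 31 & tr$height_m[!y] <= 37))
  expect_true(all(tr$rho[y] >= 3000 & tr$rho[y] <= 6500))
  expect_true(all(tr$rho[!y] >= 2500 & tr$rho[!y] <= 6000))
  expect_true(all(tr$chi >= 10 & tr$chi <= 180))
  # a tight hyper-distribution concentrates rho near mu (heavy tails
  # permit occasional excursions, so check the typical draw)
  cfg2 <- scenario_config(seed = 3, truth = list(sigma_Y = 15, sigma_O = 15))
  tr2 <- gen_trees(cfg2, default_truth(cfg2))
  expect_lt(median(abs(tr2$rho[tr2$age_group == "young"] - 4800)), 100)
})

test_that("heavy-tailed sampling matches the quadrature distribution", {
  set.seed(23)
  x <- sapflowhm:::sample_heavy_tailed(10000, 4000, 500, 2500, 6000)
  grid <- seq(2500, 6000, length.out = 2001)
  pdf <- exp(heavy_tailed_logpdf(grid, 4000, 500))
  cdf <- cumsum(c(0, (pdf[-1] + pdf[-2001]) / 2 * diff(grid)))
  cdf <- cdf / max(cdf)
  ks <- max(abs(ecdf(x)(grid) - cdf))
  expect_lt(ks, 0.02)
})

test_that("observation noise has the Laplace moment structure", {
  # old trees: mean |residual| equals the constant scale where
  # zero-truncation is negligible
  cfg <- scenario_config(n_young = 1, n_old = 5, n_days = 40, seed = 71,
                         truth = list(c_O = 0.3))
  truth <- default_truth(cfg)
  meteo <- gen_meteo(cfg)
  trees <- gen_trees(cfg, truth)
  noisy <- gen_observed_sapflow(trees, meteo, truth, cfg, noise = TRUE)
  clean <- gen_observed_sapflow(trees, meteo, truth, cfg, noise = FALSE)
  eps <- NULL; jm <- NULL
  for (id in trees$tree_id[trees$age_group == "old"]) {
    eps <- c(eps, noisy[[id]]$full$J_obs - clean[[id]]$full$J_obs)
    jm <- c(jm, clean[[id]]$full$J_obs)
  }
  big <- jm > 1.5  # > 5 scales: truncation essentially never bites
  expect_gt(sum(big), 1e4)
  expect_equal(mean(abs(eps[big])), 0.3, tolerance = 0.1 * 0.3)
  # pre-dawn rows are generated quiet (the baseline-detection premise)
  h <- unlist(lapply(trees$tree_id[trees$age_group == "old"], function(id)
    (as.numeric(noisy[[id]]$full$timestamp) / 3600) %% 24))
  expect_true(all(abs(eps[h > 3.2 & h < 5.3]) < 1e-12))
})

test_that("young-tree noise follows the saturating scale curve in bins", {
  cfg <- scenario_config(n_young = 3, n_old = 1, n_days = 30, seed = 73)
  truth <- default_truth(cfg)
  meteo <- gen_meteo(cfg)
  trees <- gen_trees(cfg, truth)
  noisy <- gen_observed_sapflow(trees, meteo, truth, cfg, noise = TRUE)
  clean <- gen_observed_sapflow(trees, meteo, truth, cfg, noise = FALSE)
  eps <- NULL; jm <- NULL
  for (id in trees$tree_id[trees$age_group == "young"]) {
    eps <- c(eps, noisy[[id]]$full$J_obs - clean[[id]]$full$J_obs)
    jm <- c(jm, clean[[id]]$full$J_obs)
  }
  keep <- jm > 1.5
  bins <- cut(jm[keep], breaks = quantile(jm[keep], seq(0, 1, 0.25)),
              include.lowest = TRUE)
  got <- tapply(abs(eps[keep]), bins, mean)
  expected <- tapply(laplace_scale_young(jm[keep], truth$a, truth$b, truth$c_Y),
                     bins, mean)
  expect_true(all(abs(got - expected) / expected < 0.1))
})

test_that("noise-free generation with grid-aligned lags is exactly self-consistent", {
  sc <- noisefree_scenario()
  r <- sapflow_residuals(sc$data, sc$truth, Ca = sc$cfg$ca_molar)
  expect_lt(max(abs(unlist(r))), 1e-12)
})

test_that("probe synthesis, preprocessing and the direct dataset agree", {
  # full self-consistency: the log-posterior at the truth computed on the
  # preprocessed probe-voltage data is within 1% of the direct one
  cfg <- scenario_config(n_young = 1, n_old = 1, n_days = 4, seed = 81)
  sc <- simulate_scenario(cfg)
  probes <- NULL; geometry <- NULL
  for (d in sc$data) {
    pv <- gen_probe_voltages(d, cfg)
    probes <- rbind(probes, pv$probes)
    geometry <- rbind(geometry, pv$geometry)
  }
  built <- build_dataset(probes, geometry, meteo_to_raw(sc$meteo), sc$trees)
  ids <- tree_ids_by_group(sc$data)
  pri <- prior_spec(ids$young, ids$old)
  lp_direct <- log_posterior(sc$truth, sc$data, pri, Ca = cfg$ca_molar)
  lp_built <- log_posterior(sc$truth, built$data, pri, Ca = cfg$ca_molar)
  expect_lt(abs(lp_built - lp_direct) / abs(lp_direct), 0.01)
})
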
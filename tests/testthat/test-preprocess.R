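test_that("Granier conversion matches the calibration power law", {
  expect_equal(granier_flux(0.8, 0.8)$J, 0)
  # (dU* - dU)/dU = 1
  expect_equal(granier_flux(0.4, 0.8)$J, 118.99e-6)
  # ratio 0.5, frozen direct evaluation
  expect_equal(granier_flux(0.8, 1.2)$J, 5.069236e-5, tolerance = 1e-6)
  expect_error(granier_flux(-0.1, 0.8), "invalid record")
})

test_that("Granier flux is monotone decreasing in dU and clamps below baseline", {
  dU <- seq(0.3, 0.9, by = 0.05)
  J <- granier_flux(dU, 0.8)$J
  expect_true(all(diff(J[dU <= 0.8]) < 0))
  res <- granier_flux(c(0.85, 0.9, 0.7), 0.8)
  expect_equal(res$J[1:2], c(0, 0))
  expect_equal(res$n_clamped, 2)
})

test_that("baseline detection flags quiet low-VPD windows and interpolates", {
  n <- 200
  bl <- detect_baseline(rep(0.8, n), rep(0, n))
  expect_true(all(bl$baseline))
  expect_equal(bl$dU_star, rep(0.8, n))
  expect_error(detect_baseline(rep(0.8, n), rep(60, n)), "no baseline")
  # noisy daytime voltage between two quiet plateaus: dU* interpolates
  dU <- rep(0.8, n)
  dU[81:120] <- 0.5 + 0.1 * sin(1:40)
  vpd <- rep(0, n); vpd[75:126] <- 500
  bl2 <- detect_baseline(dU, vpd)
  expect_false(any(bl2$baseline[81:120]))
  expect_equal(bl2$dU_star, rep(0.8, n), tolerance = 1e-12)
})

test_that("baseline voltages recover planted plateau levels within 1%", {
  cfg <- scenario_config(n_young = 1, n_old = 1, n_days = 3, seed = 31)
  sc <- simulate_scenario(cfg)
  d <- sc$data[[1]]
  pv <- gen_probe_voltages(d, cfg)
  m <- sc$meteo
  h <- (as.numeric(d$full$timestamp) / 3600) %% 24
  planted <- 0.78 + 0.001 * sin(2 * pi * (h - 3) / 24)
  one <- pv$probes[pv$probes$probe_id == pv$probes$probe_id[1], ]
  bl <- detect_baseline(one$dU_mV, m$VPD_pa)
  expect_true(any(bl$baseline))
  expect_lt(max(abs(bl$dU_star - planted) / planted), 0.01)
})

test_that("whole-tree aggregation is an annulus-area-weighted mean", {
  expect_equal(aggregate_tree(c(1, 1, 1, 1), rep(2, 4), dbh = 20), 1)
  expect_equal(aggregate_tree(c(0, 2, 0, 2), rep(2, 4), dbh = 20), 1)
  # hand-computed annulus weights 36*pi and 64*pi
  expect_equal(aggregate_tree(c(1, 2), c(2, 4), dbh = 20), 1.64)
  # probes with missing values drop out; all-missing rows yield NA
  fl <- rbind(c(1, NA), c(NA, NA))
  out <- aggregate_tree(fl, c(2, 4), dbh = 20)
  expect_equal(out, c(1, NA_real_))
})

test_that("aggregation returns a convex combination of probe fluxes", {
  set.seed(5)
  for (i in 1:20) {
    f <- runif(4, 0, 5)
    depths <- runif(4, 1, 6)
    v <- aggregate_tree(f, depths, dbh = runif(1, 15, 50))
    expect_gte(v, min(f) - 1e-12)
    expect_lte(v, max(f) + 1e-12)
  }
})

test_that("10-min resampling averages finer series onto interval ends", {
  t1 <- as.POSIXct("2018-07-09 00:01", tz = "UTC") + 60 * (0:59)
  out <- resample_10min(t1, rep(3.5, 60))
  expect_true(all(out$value == 3.5))
  expect_equal(nrow(out), 6)
  # means per 10-min block of a ramp
  out2 <- resample_10min(t1, 1:60)
  expect_equal(out2$value[1], mean(1:10))
  expect_equal(out2$value[6], mean(51:60))
})

test_that("dataset assembly drops zero-VPD rows and counts them", {
  sc <- smoke_scenario()
  d <- sc$data[[1]]
  expect_true(all(d$rows$D > 0))
  expect_equal(d$n_rows, sum(sc$meteo$D > 0))
  expect_lt(d$n_rows, nrow(d$full))
})

test_that("voltage synthesis inverts the Granier calibration exactly", {
  cfg <- scenario_config(n_young = 1, n_old = 1, n_days = 2, seed = 41)
  sc <- simulate_scenario(cfg)
  d <- sc$data[[1]]
  pv <- gen_probe_voltages(d, cfg, noise = FALSE)
  h <- (as.numeric(d$full$timestamp) / 3600) %% 24
  dU_star <- 0.78 + 0.001 * sin(2 * pi * (h - 3) / 24)
  # each probe carries a known multiple of the tree flux
  for (p in unique(pv$probes$probe_id)) {
    one <- pv$probes[pv$probes$probe_id == p, ]
    J <- molar_flux(granier_flux(one$dU_mV, dU_star)$J)
    ref <- d$full$J_obs * J[which.max(d$full$J_obs)] / max(d$full$J_obs)
    nz <- d$full$J_obs > 0
    expect_lt(max(abs(J[nz] - ref[nz]) / ref[nz]), 1e-9)
  }
  # zero flux maps back to the baseline voltage
  z <- pv$probes$dU_mV[rep(d$full$J_obs == 0, 4)]
  expect_equal(z, rep(dU_star, 4)[rep(d$full$J_obs == 0, 4)], tolerance = 1e-12)
})

test_that("full preprocessing recovers the planted whole-tree flux within 2%", {
  cfg <- scenario_config(n_young = 1, n_old = 1, n_days = 3, seed = 51)
  sc <- simulate_scenario(cfg)
  probes <- NULL; geometry <- NULL
  for (d in sc$data) {
    pv <- gen_probe_voltages(d, cfg)
    probes <- rbind(probes, pv$probes)
    geometry <- rbind(geometry, pv$geometry)
  }
  trees <- sc$trees
  built <- build_dataset(probes, geometry, meteo_to_raw(sc$meteo), trees)
  for (id in trees$tree_id) {
    planted <- sc$data[[id]]$full$J_obs
    got <- built$data[[id]]$full$J_obs
    big <- planted > 0.25 * max(planted)  # away from baseline windows
    expect_lt(max(abs(got[big] - planted[big]) / planted[big]), 0.02)
  }
  expect_true(all(built$qc$n_baseline_points > 0))
})
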
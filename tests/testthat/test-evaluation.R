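test_that("RMSE and normalised RMSE follow their definitions", {
  expect_equal(rmse(rep(0, 10)), 0)
  expect_equal(rmse(c(3, 4)), sqrt(25 / 2))
  expect_equal(rmse(c(3, 4)), 3.5355, tolerance = 1e-4)
  expect_equal(rmse_pct(c(2, 2), c(1, 3)), 100)
  # scale invariance
  e <- rnorm(50); j <- runif(50, 1, 5)
  expect_equal(rmse_pct(e, j), rmse_pct(3.7 * e, 3.7 * j))
  expect_error(rmse(numeric(0)), "empty")
  expect_error(rmse_pct(1, -1), "positive")
})

test_that("lag-height regression through the origin reproduces the published fit", {
  tab <- published_tables()
  fit <- chi_height_regression(tab$chi_min, tab$height_m)
  expect_equal(fit$slope, 4.7266, tolerance = 1e-4)
  expect_equal(fit$r_squared, 0.8153, tolerance = 1e-4)
  # exact proportionality gives R^2 = 1
  expect_equal(chi_height_regression(3 * (1:5), 1:5)$r_squared, 1)
})

test_that("leaf-sapwood ratio regression finds and excludes the influential tree", {
  tab <- published_tables()
  reg <- rho_height_regression(setNames(tab$rho, tab$tree_id), tab$height_m)
  expect_equal(reg$all$slope, -0.008103, tolerance = 1e-3)
  expect_equal(unname(reg$cooks["O3"]), 0.6789, tolerance = 1e-3)
  expect_identical(reg$excluded_point, "O3")
  expect_equal(reg$excluded$slope, -0.011773, tolerance = 1e-3)
  expect_equal(reg$excluded$r_squared, 0.6240, tolerance = 1e-3)
  # collinear points give a perfect fit
  col <- rho_height_regression(1e4 * (0.9 - 0.01 * (1:5)), 1:5)
  expect_equal(col$all$r_squared, 1)
})

test_that("standardised slope rescales by the sample maxima", {
  expect_equal(standardized_slope(0, c(1, 2), c(3, 4)), 0)
  # published unrounded slope with the table maxima
  expect_equal(standardized_slope(-0.0123, 0.6493, 36.8), -0.697, tolerance = 1e-3)
  expect_equal(standardized_slope(-0.011773, 0.6493, 36.8), -0.667, tolerance = 1e-3)
})

test_that("observed-versus-modelled regression behaves at its extremes", {
  x <- runif(200, 0, 5)
  perfect <- obs_vs_mod_regression(x, x)
  expect_equal(perfect$slope, 1)
  expect_equal(perfect$r_squared, 1)
  set.seed(13)
  noise <- obs_vs_mod_regression(x, rnorm(200))
  expect_lt(noise$r_squared, 0.05)
})

test_that("uncertainty bands nest and collapse in the degenerate limits", {
  sc <- smoke_scenario()
  nm <- names(sc$truth)
  draws <- matrix(rep(sc$truth, 120), nrow = 120, byrow = TRUE,
                  dimnames = list(NULL, nm))
  bands <- predictive_bands(sc$data, draws, Ca = sc$cfg$ca_molar, seed = 2)
  for (b in bands) {
    # degenerate posterior: parametric band has zero width
    expect_equal(b$param_lo, b$param_hi)
    expect_true(all(b$pred_lo <= b$param_lo + 1e-12))
    expect_true(all(b$pred_hi >= b$param_hi - 1e-12))
    expect_true(all(b$pred_lo >= 0))
  }
  # noise scale at its lower bound: predictive collapses onto parametric
  tiny <- draws
  tiny[, c("c_Y", "c_O")] <- 1e-3
  tiny[, grep("^a_", nm)] <- 1e-3
  bt <- predictive_bands(sc$data, tiny, Ca = sc$cfg$ca_molar, seed = 2)
  for (b in bt) expect_lt(max(b$pred_hi - b$param_hi), 0.05)
})

test_that("cross-validation folds partition the first eight days", {
  sc <- fixture("cv_noisy", function() simulate_scenario(
    scenario_config(n_young = 2, n_old = 2, n_days = 9, seed = 61)))
  days <- sort(unique(as.Date(sc$data[[1]]$full$timestamp)))[1:8]
  held <- lapply(days, function(day) {
    sum(vapply(sc$data, function(d) sum(as.Date(d$rows$timestamp) == day),
               integer(1)))
  })
  total_first8 <- sum(vapply(sc$data, function(d)
    sum(as.Date(d$rows$timestamp) %in% days), integer(1)))
  expect_equal(sum(unlist(held)), total_first8)
  expect_true(all(unlist(held) > 0))
})

test_that("cross-validation on noise-free data returns zero held-out error", {
  sc <- noisefree_scenario()
  cv <- cross_validate(sc$data, mode = "fix_iota", theta_map_full = sc$truth,
                       Ca = sc$cfg$ca_molar, seed = 3)
  expect_equal(nrow(cv$summary), 8L)
  expect_true(all(cv$summary$rmse_holdout < 1e-6))
})

test_that("cross-validation on noisy data has stable held-out error", {
  sc <- fixture("cv_noisy", function() simulate_scenario(
    scenario_config(n_young = 2, n_old = 2, n_days = 9, seed = 61)))
  ids <- tree_ids_by_group(sc$data)
  pri <- prior_spec(ids$young, ids$old)
  lp <- make_log_posterior(sc$data, pri, Ca = sc$cfg$ca_molar)
  nm <- attr(lp, "param_names")
  pp <- pri[match(nm, pri$name), ]
  start <- setNames(pmin(pmax(sc$truth[nm], pp$lower), pp$upper), nm)
  map_full <- sapflowhm:::optimise_mode_global(lp, start, pp$lower, pp$upper, nm,
                                              rounds = 1)$theta
  for (mode in c("fix_iota", "fix_gamma")) {
    cv <- cross_validate(sc$data, mode = mode, theta_map_full = map_full,
                         Ca = sc$cfg$ca_molar, seed = 3)
    r <- cv$summary$rmse_holdout
    expect_lt(sd(r) / mean(r), 0.5)
  }
})
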
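test_that("lagged observation interpolates between the bracketing grid points", {
  J <- c(rep(0, 7), 1.0, 2.0, 4.0, 3.0)
  # chi an exact grid multiple: degenerate interpolation
  expect_equal(lagged_observation(J, 70, at = 1L), J[8])
  # midpoint
  expect_equal(lagged_observation(c(rep(0, 7), 2, 4), 75, at = 1L), 3)
  # chi = 74.3: proximity weights (5.7, 4.3)/10
  expect_equal(lagged_observation(J, 74.3, at = 1L), (5.7 * 1 + 4.3 * 2) / 10)
  # printed convention attaches (chi - t0) to the earlier point
  expect_equal(lagged_observation(J, 74.3, at = 1L, interp = "printed"),
               (4.3 * 1 + 5.7 * 2) / 10)
  # lag lookups beyond the series are NA
  expect_true(is.na(lagged_observation(J, 74.3, at = 4L)))
})

test_that("young-tree Laplace scale saturates between c and c + b", {
  expect_equal(laplace_scale_young(0, 0.5, 1, 0.1), 0.1)
  expect_equal(laplace_scale_young(1e9, 0.5, 1, 0.1), 1.1, tolerance = 1e-6)
  expect_equal(laplace_scale_young(2, 0.5, 1, 0.1), 0.6)
  expect_error(laplace_scale_young(1, -0.5, 1, 0.1))
})

test_that("heavy-tailed prior density is normalised, symmetric and continuous", {
  # z -> 0 analytic limit
  expect_equal(heavy_tailed_logpdf(5, 5, 1), log(1 / (2 * sqrt(2 * pi))))
  expect_equal(heavy_tailed_logpdf(5, 5, 1), -1.6121, tolerance = 1e-4)
  for (s in c(0.1, 1, 500)) {
    int <- integrate(function(x) exp(heavy_tailed_logpdf(x, 0, s)),
                     -Inf, Inf, rel.tol = 1e-10)
    expect_equal(int$value, 1, tolerance = 1e-6)
  }
  # 1/z^2 tails: density ratio at 10 and 20 sigma is ~4
  expect_equal(exp(heavy_tailed_logpdf(10, 0, 1) - heavy_tailed_logpdf(20, 0, 1)),
               4, tolerance = 0.01)
  expect_equal(heavy_tailed_logpdf(3, 10, 2), heavy_tailed_logpdf(17, 10, 2))
  # continuity of the removable singularity
  expect_lt(abs(exp(heavy_tailed_logpdf(5 + 1e-8, 5, 1)) -
                exp(heavy_tailed_logpdf(5, 5, 1))), 1e-12)
})

test_that("parameter counts match the model structure", {
  pc <- count_parameters(5, 6)
  expect_identical(pc$total, 44L)
  expect_identical(pc$direct, 28L)
  pc2 <- count_parameters(1, 1)
  expect_identical(pc2$total, pc2$direct + 2L + 6L)
  expect_identical(length(param_names(paste0("Y", 1:5), paste0("O", 1:6))), 44L)
})

test_that("residuals vanish on self-generated noise-free data", {
  sc <- noisefree_scenario()  # grid-multiple lags
  r <- sapflow_residuals(sc$data, sc$truth, Ca = sc$cfg$ca_molar)
  expect_lt(max(abs(unlist(r))), 1e-12)
  # +10% on one tree's rho scales its residuals by -0.1 J_mod
  th <- sc$truth
  id <- sc$trees$tree_id[1]
  th[paste0("rho_", id)] <- 1.1 * th[paste0("rho_", id)]
  r2 <- sapflow_residuals(sc$data, th, Ca = sc$cfg$ca_molar)
  d <- sc$data[[id]]
  p <- stomatal_params(th[["lambda_Y"]], th[["iota_Y"]], th[["gamma_Y"]])
  Jm <- modeled_sapflow(d$rows$D, d$rows$I, p, sc$truth[paste0("rho_", id)],
                        sc$cfg$ca_molar)
  n <- length(r2[[id]])
  expect_equal(r2[[id]], (-0.1 * Jm)[seq_len(n)], tolerance = 1e-10)
})

test_that("misspecifying the lag by one grid step shifts the matched observation", {
  sc <- noisefree_scenario()
  id <- sc$trees$tree_id[1]
  th <- sc$truth
  th[paste0("chi_", id)] <- th[paste0("chi_", id)] + 10
  r <- sapflow_residuals(sc$data[id], th, Ca = sc$cfg$ca_molar)[[id]]
  d <- sc$data[[id]]
  at <- which(d$valid)
  k <- (sc$truth[paste0("chi_", id)] + 10) / 10
  ok <- at + k <= nrow(d$full)
  shift <- d$full$J_obs[at[ok] + k] - d$full$J_obs[at[ok] + k - 1]
  # residual equals the lag-10 first difference of the observed series
  expect_equal(r, shift, tolerance = 1e-10)
})

test_that("Laplace log-likelihood matches its closed form", {
  # -log(2s) - |eps|/s
  expect_equal(laplace_logdens(0, 0.5), 0)
  expect_equal(laplace_logdens(1, 1), -log(2) - 1)
  e <- seq(0, 3, by = 0.5)
  expect_true(all(diff(laplace_logdens(e, 1)) < 0))
})

test_that("log-likelihood of a constructed single-point dataset is exact", {
  ts <- as.POSIXct("2018-07-09 00:10", tz = "UTC") + 600 * (0:19)
  # one old tree, constant drivers; chi = 30 min exactly
  D <- rep(0.4, 20); I <- rep(1e-3, 20); Ca <- rep(1.701e-2, 20)
  p <- stomatal_params(1.124e-3, 0.520, 2.625e-3)
  Jm <- modeled_sapflow(0.4, 1e-3, p, 4000, 1.701e-2)
  J_obs <- rep(Jm, 20)
  d <- tree_dataset("O1", "old", 33, 48, 160, ts, J_obs, D, I, Ca)
  ids <- param_names("Y0", "O1")  # dummy young id unused by this dataset
  th <- setNames(rep(1, length(ids)), ids)
  th[c("lambda_O", "iota_O", "gamma_O")] <- c(1.124e-3, 0.520, 2.625e-3)
  th["rho_O1"] <- 4000; th["chi_O1"] <- 30; th["c_O"] <- 0.5
  th[c("mu_Y", "mu_O", "sigma_Y", "sigma_O")] <- c(4000, 4000, 500, 500)
  ll <- log_likelihood(list(O1 = d), th, Ca = 1.701e-2)
  # 17 usable rows, each with eps = 0 and scale 0.5: -log(2*0.5) = 0 each
  expect_equal(ll, 0)
  # one unit of residual at scale 1
  d2 <- tree_dataset("O1", "old", 33, 48, 160, ts, J_obs + 1, D, I, Ca)
  th["c_O"] <- 1
  ll2 <- log_likelihood(list(O1 = d2), th, Ca = 1.701e-2)
  expect_equal(ll2, 17 * (-log(2) - 1))
})

test_that("log-prior enforces bounds and sums the heavy-tailed terms", {
  yid <- c("Y1", "Y2"); oid <- c("O1", "O2")
  pri <- prior_spec(yid, oid)
  th <- setNames((pri$lower + pri$upper) / 2, pri$name)
  th[c("rho_Y1", "rho_Y2")] <- th["mu_Y"]
  th[c("rho_O1", "rho_O2")] <- th["mu_O"]
  lp <- log_prior(th, pri)
  expect_equal(lp, 2 * log(1 / (2 * th[["sigma_Y"]] * sqrt(2 * pi))) +
                 2 * log(1 / (2 * th[["sigma_O"]] * sqrt(2 * pi))))
  th_bad <- th; th_bad["iota_Y"] <- 1.3
  expect_identical(log_prior(th_bad, pri), -Inf)
  # uniform-prior parameters do not change the log-prior inside bounds
  th2 <- th; th2["chi_Y1"] <- th2["chi_Y1"] + 30
  expect_equal(log_prior(th2, pri), lp)
})

test_that("log-posterior is maximal at the generating parameters (coarse scan)", {
  sc <- noisefree_scenario()
  ids <- tree_ids_by_group(sc$data)
  pri <- prior_spec(ids$young, ids$old)
  lp <- make_log_posterior(sc$data, pri, Ca = sc$cfg$ca_molar)
  base <- lp(sc$truth)
  expect_identical(lp(sc$truth * NA), -Inf)
  for (nm in c("lambda_Y", "iota_O", "gamma_Y", "rho_O1", "chi_Y2")) {
    for (fac in c(0.9, 0.97, 1.03, 1.1)) {
      th <- sc$truth
      th[nm] <- th[nm] * fac
      expect_lt(lp(th), base)
    }
  }
})

test_that("likelihood is invariant under time translation of data and drivers", {
  sc <- smoke_scenario()
  ids <- tree_ids_by_group(sc$data)
  pri <- prior_spec(ids$young, ids$old)
  ll1 <- log_likelihood(sc$data, sc$truth, Ca = sc$cfg$ca_molar)
  shifted <- lapply(sc$data, function(d) {
    tree_dataset(d$tree_id, d$age_group, d$height, d$dbh, d$age,
                 d$full$timestamp + 86400, d$full$J_obs, d$full$D,
                 d$full$I, d$full$Ca)
  })
  ll2 <- log_likelihood(shifted, sc$truth, Ca = sc$cfg$ca_molar)
  expect_equal(ll1, ll2)
})

test_that("likelihood is exchangeable across trees within an age group", {
  sc <- smoke_scenario()
  d1 <- sc$data[["O1"]]; d2 <- sc$data[["O2"]]
  # give both old trees identical data; swapping their rho/chi must not matter
  d2b <- tree_dataset("O2", "old", d2$height, d2$dbh, d2$age,
                      d1$full$timestamp, d1$full$J_obs, d1$full$D,
                      d1$full$I, d1$full$Ca)
  dat <- list(O1 = d1, O2 = d2b, Y1 = sc$data[["Y1"]], Y2 = sc$data[["Y2"]])
  th <- sc$truth
  ll1 <- log_likelihood(dat, th, Ca = sc$cfg$ca_molar)
  th2 <- th
  th2[c("rho_O1", "rho_O2")] <- th[c("rho_O2", "rho_O1")]
  th2[c("chi_O1", "chi_O2")] <- th[c("chi_O2", "chi_O1")]
  ll2 <- log_likelihood(dat, th2, Ca = sc$cfg$ca_molar)
  expect_equal(ll1, ll2)
})
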
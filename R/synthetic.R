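#' Configuration of a synthetic sap flow scenario
#'
#' Defines the study design the generator emulates: a boreal Scots pine
#' campaign with five young and six old trees observed for eight or
#' more days on a 10-min grid, diurnal light and vapour-deficit drivers
#' with moderate positive correlation, and Laplace-distributed
#' observation noise (heteroscedastic in the young stand).
#'
#' @param n_young,n_old numbers of trees per age group.
#' @param n_days length of the campaign (days).
#' @param seed integer seed; all generator randomness derives from it.
#' @param i_peak clear-sky midday PPFD (mol m^-2 s^-1).
#' @param cloud_min lower bound of the cloud transmission multiplier.
#' @param cloud_ar lag-1 autocorrelation of the cloud process.
#' @param t_range diurnal air temperature range (degC).
#' @param hr_range relative humidity range (%); the upper end is reached
#'   pre-dawn so that zero-VPD rows occur and exercise the D-filter.
#' @param ca_molar CO2 concentration (mol m^-3), constant.
#' @param chi_per_height slope of the lag-height relation (min m^-1).
#' @param chi_sd tree-to-tree lag scatter (min).
#' @param voltage_noise_sd probe voltage noise, relative to the baseline
#'   voltage.
#' @param truth optional named list overriding any default true
#'   parameter (see [default_truth()]).
#' @param dt_min grid step (minutes).
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(n_young = 5, n_old = 6, n_days = 8, seed = 1,
                            i_peak = 1.5e-3, cloud_min = 0.2, cloud_ar = 0.97,
                            t_range = c(10, 25), hr_range = c(40, 100),
                            ca_molar = 1.701e-2,
                            chi_per_height = 4.74, chi_sd = 8,
                            voltage_noise_sd = 0.002,
                            truth = list(), dt_min = 10) {
  stopifnot(n_days >= 1, n_young >= 1, n_old >= 1)
  structure(list(n_young = n_young, n_old = n_old, n_days = n_days,
                 seed = seed, i_peak = i_peak, cloud_min = cloud_min,
                 cloud_ar = cloud_ar, t_range = t_range, hr_range = hr_range,
                 ca_molar = ca_molar, chi_per_height = chi_per_height,
                 chi_sd = chi_sd, voltage_noise_sd = voltage_noise_sd,
                 truth = truth, dt_min = dt_min),
            class = "scenario_config")
}

#' Default true parameter values of the synthetic scenario
#'
#' Group-level stomatal parameters sit well inside the prior boxes near
#' the magnitudes a mature boreal pine stand exhibits (young trees with
#' a steeper light response and higher marginal water cost than old);
#' noise scales give whole-data normalised RMSE in the tens of percent,
#' as thermal-dissipation field data show.
#'
#' @param cfg a [scenario_config()]; entries of `cfg$truth` override
#'   the defaults.
#' @return named list of true values (tree-level rho/chi are drawn by
#'   [gen_trees()], not set here).
#' @export
default_truth <- function(cfg) {
  tv <- list(lambda_Y = 2.2e-3, lambda_O = 1.1e-3,
             iota_Y = 0.90, iota_O = 0.52,
             gamma_Y = 2.59e-3, gamma_O = 2.63e-3,
             a = 0.4, b = 1.5, c_Y = 0.3, c_O = 0.7,
             mu_Y = 4800, sigma_Y = 700, mu_O = 3600, sigma_O = 600)
  utils::modifyList(tv, cfg$truth)
}

#' Generate the 10-min meteorological driver series
#'
#' PPFD is a clear-sky half-sine (day spanning 04:00-22:00, high-summer
#' boreal daylight) times a lag-1 autocorrelated cloud-transmission
#' multiplier in `(cloud_min, 1]`; temperature follows a diurnal
#' sinusoid; relative humidity runs in anti-phase with temperature and
#' touches 100% pre-dawn, producing genuine zero-VPD rows; the vapour
#' deficit D follows from [vpd_pa()] and [vpd_molar()]. The realised
#' daytime Pearson correlation of D and PPFD is required to fall in
#' \[0.3, 0.8\] (moderate coupling); the cloud process is redrawn up to
#' 10 times before a mis-tuned configuration is reported.
#'
#' @param cfg a [scenario_config()].
#' @return data.frame: `timestamp` (POSIXct, end-of-interval labels),
#'   `T_C`, `RH_pct`, `I`, `VPD_pa`, `D`, `Ca`.
#' @export
gen_meteo <- function(cfg) {
  set.seed(cfg$seed + 1L)
  n <- cfg$n_days * (1440L %/% cfg$dt_min)
  t0 <- as.POSIXct("2018-07-09 00:00:00", tz = "UTC")
  ts <- t0 + seq_len(n) * cfg$dt_min * 60
  h <- ((as.numeric(ts) - as.numeric(t0)) / 3600) %% 24
  day_frac <- pmax(sin(pi * (h - 4) / 18), 0) * (h > 4 & h < 22)
  tmin <- cfg$t_range[1]; tmax <- cfg$t_range[2]
  diurnal <- 0.5 * (1 - cos(2 * pi * (h - 5) / 24))
  hrmin <- cfg$hr_range[1]; hrmax <- cfg$hr_range[2]
  for (try in seq_len(10L)) {
    x <- stats::filter(stats::rnorm(n, 0, sqrt(1 - cfg$cloud_ar^2)),
                       cfg$cloud_ar, method = "recursive")
    cloud <- cfg$cloud_min + (1 - cfg$cloud_min) * stats::pnorm(as.numeric(x))
    I <- cfg$i_peak * day_frac * cloud
    # overcast spells damp the diurnal temperature amplitude (and hence
    # VPD), which keeps D and I positively coupled as observed
    csm <- stats::filter(cloud, rep(1 / 18, 18), sides = 1)
    csm[is.na(csm)] <- cloud[is.na(csm)]
    T_C <- tmin + (tmax - tmin) * diurnal * (0.45 + 0.55 * as.numeric(csm))
    RH <- hrmax - (hrmax - hrmin) * (T_C - tmin) / (tmax - tmin) +
      stats::rnorm(n, 0, 2)
    RH <- pmin(pmax(RH, 0), 100)
    vp <- vpd_pa(T_C, RH)
    D <- vpd_molar(vp, T_C)
    day <- I > 0
    r <- stats::cor(D[day], I[day])
    if (r >= 0.3 && r <= 0.8) {
      return(data.frame(timestamp = ts, T_C = T_C, RH_pct = RH, I = I,
                        VPD_pa = vp, D = D, Ca = cfg$ca_molar))
    }
  }
  stop("gen_meteo: daytime cor(D, I) outside [0.3, 0.8] after 10 redraws; ",
       "re-tune the driver configuration")
}

# inverse-CDF sampling from the heavy-tailed density truncated to [lo, hi]
sample_heavy_tailed <- function(n, mu, sigma, lo, hi, grid_n = 4096) {
  x <- seq(lo, hi, length.out = grid_n)
  pdf <- exp(heavy_tailed_logpdf(x, mu, sigma))
  cdf <- cumsum(c(0, (pdf[-1] + pdf[-grid_n]) / 2 * diff(x)))
  cdf <- cdf / cdf[grid_n]
  stats::approx(cdf, x, xout = stats::runif(n), ties = "ordered")$y
}

#' Generate tree metadata and true tree-level parameters
#'
#' Heights are uniform over the spans of the two age groups (young
#' 16-21 m, old 31-37 m); each tree's true leaf-sapwood ratio is drawn
#' from the heavy-tailed distribution of its group (numeric inverse
#' CDF) truncated to the prior box, and its true time lag follows the
#' lag-height relation `chi = chi_per_height * H + N(0, chi_sd)`,
#' clipped to \[10, 180\] min.
#'
#' @param cfg a [scenario_config()].
#' @param truth named list from [default_truth()].
#' @return data.frame: `tree_id`, `age_group`, `height_m`, `dbh_cm`,
#'   `age_yr`, `rho`, `chi`.
#' @export
gen_trees <- function(cfg, truth = default_truth(cfg)) {
  set.seed(cfg$seed + 2L)
  nY <- cfg$n_young; nO <- cfg$n_old
  ids <- c(paste0("Y", seq_len(nY)), paste0("O", seq_len(nO)))
  ag <- c(rep("young", nY), rep("old", nO))
  H <- c(stats::runif(nY, 16, 21), stats::runif(nO, 31, 37))
  dbh <- c(stats::runif(nY, 17, 24), stats::runif(nO, 43, 52))
  age <- c(round(stats::runif(nY, 50, 52)), round(stats::runif(nO, 130, 180)))
  rho <- c(sample_heavy_tailed(nY, truth$mu_Y, truth$sigma_Y, 3000, 6500),
           sample_heavy_tailed(nO, truth$mu_O, truth$sigma_O, 2500, 6000))
  chi <- pmin(pmax(cfg$chi_per_height * H + stats::rnorm(nY + nO, 0, cfg$chi_sd),
                   10), 180)
  data.frame(tree_id = ids, age_group = ag, height_m = H, dbh_cm = dbh,
             age_yr = age, rho = rho, chi = chi)
}

#' Generate observed sap flow for every tree
#'
#' Runs the process model forward at the true parameters over the full
#' driver grid (transpiration zero where D = 0), lags it by each tree's
#' true `chi` with the same linear-interpolation convention the
#' likelihood uses, adds Laplace noise (young: heteroscedastic scale of
#' [laplace_scale_young()]; old: constant `c_O`), and truncates at
#' zero. Zero-D rows are retained in the full grid so that downstream
#' filtering is exercised.
#'
#' @param trees a [gen_trees()] table.
#' @param meteo a [gen_meteo()] table.
#' @param truth named list from [default_truth()].
#' @param cfg a [scenario_config()].
#' @param noise add observation noise (default TRUE).
#' @return named list of [tree_dataset()] objects.
#' @export
gen_observed_sapflow <- function(trees, meteo, truth, cfg, noise = TRUE) {
  set.seed(cfg$seed + 3L)
  n <- nrow(meteo)
  tnum <- as.numeric(meteo$timestamp)
  out <- list()
  for (i in seq_len(nrow(trees))) {
    tr <- trees[i, ]
    young <- tr$age_group == "young"
    p <- if (young) {
      stomatal_params(truth$lambda_Y, truth$iota_Y, truth$gamma_Y)
    } else {
      stomatal_params(truth$lambda_O, truth$iota_O, truth$gamma_O)
    }
    E <- numeric(n)
    ok <- meteo$D > 0
    E[ok] <- transpiration(meteo$D[ok], meteo$I[ok], p, cfg$ca_molar)
    Jm <- tr$rho * E
    J_lag <- stats::approx(tnum, Jm, xout = tnum - tr$chi * 60, rule = 2)$y
    if (noise) {
      s <- if (young) laplace_scale_young(J_lag, truth$a, truth$b, truth$c_Y)
           else rep(truth$c_O, n)
      # pre-dawn zero-flow spells are quiet in real thermal-dissipation
      # records (the basis of baseline detection); ramp the observation
      # noise out over 03:00-05:30 so the synthetic probes behave alike
      h <- ((tnum / 3600) %% 24)
      dist_out <- pmax(pmax(3 - h, h - 5.5), 0)
      w <- pmin(dist_out / 0.75, 1)
      J_obs <- pmax(J_lag + rlaplace(n, s) * w, 0)
    } else {
      J_obs <- J_lag
    }
    out[[tr$tree_id]] <- tree_dataset(
      tree_id = tr$tree_id, age_group = tr$age_group, height = tr$height_m,
      dbh = tr$dbh_cm, age = tr$age_yr,
      timestamp = meteo$timestamp, J_obs = J_obs,
      D = meteo$D, I = meteo$I, Ca = meteo$Ca, dt_min = cfg$dt_min
    )
  }
  out
}

#' Synthesise thermal-dissipation probe voltages for a tree
#'
#' Inverts the Granier calibration: four probes with distinct sapwood
#' depths carry radial multiples of the tree-level flux constructed so
#' that the annulus-weighted aggregation returns exactly the planted
#' series; a slowly varying diurnal baseline voltage is chosen and the
#' voltage difference solved from
#' \eqn{\Delta U = \Delta U^*/(1 + (J/118.99\times10^{-6})^{1/1.231})},
#' plus Gaussian voltage noise. Pre-dawn windows satisfy both baseline
#' criteria (the driver generator guarantees near-zero VPD there).
#'
#' @param tree a [tree_dataset()] whose `full$J_obs` is the planted
#'   molar flux series.
#' @param cfg a [scenario_config()].
#' @param noise add voltage noise (default TRUE).
#' @return list with `probes` (long data.frame: tree_id, probe_id,
#'   azimuth, timestamp, dU_mV) and `geometry` (tree_id, probe_id,
#'   azimuth, mount_height_cm, sapwood_depth_cm).
#' @export
gen_probe_voltages <- function(tree, cfg, noise = TRUE) {
  set.seed(cfg$seed + 4L + sum(utf8ToInt(tree$tree_id)))
  ts <- tree$full$timestamp
  n <- length(ts)
  h <- (as.numeric(ts) / 3600) %% 24
  # slow diurnal baseline drift; thermal-dissipation baselines move by
  # well under a percent per day, and the pre-dawn anchor points must
  # represent the whole day to the stated recovery tolerance
  dU_star <- 0.78 + 0.001 * sin(2 * pi * (h - 3) / 24)
  azimuth <- c("NW", "SE", "SW", "NE")
  mount <- c(130, 130, 115, 115)
  depth <- 0.075 * tree$dbh * c(0.85, 0.95, 1.05, 1.15)
  r_out <- tree$dbh / 2
  w <- r_out^2 - pmax(r_out - depth, 0)^2
  raw <- c(0.85, 0.95, 1.05, 1.15)
  mult <- raw / (sum(w * raw) / sum(w))  # annulus-weighted mean of mult is 1
  probes <- NULL
  for (k in 1:4) {
    J_ms <- tree$full$J_obs * mult[k] / sapflow_constants$water_molar_density
    ratio <- (J_ms / sapflow_constants$granier_coef)^(1 / sapflow_constants$granier_exp)
    dU <- dU_star / (1 + ratio)
    # noise enters at the 1-min reading level; the recorded 10-min means
    # carry sd/sqrt(10)
    if (noise) dU <- dU + stats::rnorm(n, 0, cfg$voltage_noise_sd * dU_star / sqrt(10))
    probes <- rbind(probes, data.frame(
      tree_id = tree$tree_id, probe_id = paste0(tree$tree_id, "_", azimuth[k]),
      azimuth = azimuth[k], timestamp = ts, dU_mV = dU
    ))
  }
  geometry <- data.frame(
    tree_id = tree$tree_id, probe_id = paste0(tree$tree_id, "_", azimuth),
    azimuth = azimuth, mount_height_cm = mount, sapwood_depth_cm = depth
  )
  list(probes = probes, geometry = geometry)
}

#' Generate a complete synthetic scenario
#'
#' Drivers, trees, true parameter vector and per-tree observed sap flow
#' in one seeded call; the returned truth vector is laid out exactly as
#' [param_names()] so recovery can be scored directly.
#'
#' @param cfg a [scenario_config()].
#' @param noise add observation noise (default TRUE).
#' @return list with `data` (list of [tree_dataset()]), `truth` (named
#'   vector), `trees`, `meteo`, `cfg`.
#' @export
simulate_scenario <- function(cfg = scenario_config(), noise = TRUE) {
  truth <- default_truth(cfg)
  meteo <- gen_meteo(cfg)
  trees <- gen_trees(cfg, truth)
  data <- gen_observed_sapflow(trees, meteo, truth, cfg, noise = noise)
  list(data = data, truth = truth_vector(trees, truth), trees = trees,
       meteo = meteo, cfg = cfg)
}

#' Assemble the full named true parameter vector of a scenario
#'
#' Combines the group-level truths with the tree-level `rho`/`chi`
#' draws into the canonical [param_names()] layout.
#'
#' @param trees a [gen_trees()] table (with `rho` and `chi` columns).
#' @param truth named list from [default_truth()].
#' @return named numeric vector of length [count_parameters()]`$total`.
#' @export
truth_vector <- function(trees, truth) {
  yid <- trees$tree_id[trees$age_group == "young"]
  oid <- trees$tree_id[trees$age_group == "old"]
  theta <- c(
    lambda_Y = truth$lambda_Y, lambda_O = truth$lambda_O,
    iota_Y = truth$iota_Y, iota_O = truth$iota_O,
    gamma_Y = truth$gamma_Y, gamma_O = truth$gamma_O,
    stats::setNames(trees$rho, paste0("rho_", trees$tree_id)),
    stats::setNames(trees$chi, paste0("chi_", trees$tree_id)),
    stats::setNames(rep(truth$a, length(yid)), paste0("a_", yid)),
    stats::setNames(rep(truth$b, length(yid)), paste0("b_", yid)),
    c_Y = truth$c_Y, c_O = truth$c_O,
    mu_Y = truth$mu_Y, mu_O = truth$mu_O,
    sigma_Y = truth$sigma_Y, sigma_O = truth$sigma_O
  )
  theta[param_names(yid, oid)]
}

#' Back out raw meteorology files from a generated driver table
#'
#' Produces the CSV-dialect input [build_dataset()] consumes (CO2 as a
#' mixing ratio consistent with the constant molar concentration).
#'
#' @param meteo a [gen_meteo()] table.
#' @return data.frame: `timestamp`, `T_C`, `RH_pct`, `PPFD_mol_m2_s`,
#'   `CO2_ppm`.
#' @export
meteo_to_raw <- function(meteo) {
  ppm <- meteo$Ca * sapflow_constants$R_gas * (meteo$T_C + 273.15) /
    sapflow_constants$P0 * 1e6
  data.frame(timestamp = meteo$timestamp, T_C = meteo$T_C,
             RH_pct = meteo$RH_pct, PPFD_mol_m2_s = meteo$I, CO2_ppm = ppm)
}
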
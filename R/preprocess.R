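#' Detect zero-flow baseline voltages of a thermal-dissipation probe
#'
#' A timestamp is a baseline point iff, over a 2-hour window centred on
#' it, (1) the mean vapour pressure deficit is at most `vpd_limit` Pa and
#' (2) the standard deviation of the probe voltage difference is at most
#' `rel_sd_limit` (per mille fraction) of its mean over the same window.
#' The zero-flow voltage \eqn{\Delta U^*(t)} is obtained by linear
#' interpolation between successive baseline points, with constant
#' extrapolation beyond the first/last.
#'
#' @param dU probe voltage difference (mV), one value per 10-min step.
#' @param vpd vapour pressure deficit (Pa) on the same timestamps.
#' @param probe_id label used in error messages.
#' @param vpd_limit maximum window-mean VPD (Pa), default 50.
#' @param rel_sd_limit maximum window sd of dU relative to its window
#'   mean, default 0.005 (5 per mille).
#' @param window_min window length in minutes, default 120 (centred).
#' @param dt_min series time step in minutes, default 10.
#' @return list with `baseline` (logical per timestamp) and `dU_star`
#'   (numeric per timestamp).
#' @export
detect_baseline <- function(dU, vpd, probe_id = "probe",
                            vpd_limit = 50, rel_sd_limit = 0.005,
                            window_min = 120, dt_min = 10) {
  stopifnot(length(dU) == length(vpd))
  n <- length(dU)
  k <- floor(window_min / dt_min) + 1L  # centred window, odd point count
  if (k %% 2L == 0L) k <- k + 1L
  mean_vpd <- zoo::rollapply(vpd, k, mean, na.rm = TRUE,
                             fill = NA, partial = TRUE, align = "center")
  mean_du <- zoo::rollapply(dU, k, mean, na.rm = TRUE,
                            fill = NA, partial = TRUE, align = "center")
  sd_du <- zoo::rollapply(dU, k, stats::sd, na.rm = TRUE,
                          fill = NA, partial = 2, align = "center")
  baseline <- !is.na(mean_vpd) & !is.na(sd_du) & !is.na(mean_du) &
    mean_vpd <= vpd_limit & sd_du <= rel_sd_limit * mean_du & !is.na(dU)
  if (!any(baseline)) {
    stop("no baseline point found for ", probe_id,
         ": series never satisfies the low-VPD / stable-voltage criteria")
  }
  idx <- which(baseline)
  if (length(idx) == 1L) {
    dU_star <- rep(dU[idx], n)
  } else {
    dU_star <- stats::approx(idx, dU[idx], xout = seq_len(n), rule = 2)$y
  }
  list(baseline = baseline, dU_star = dU_star)
}

#' Granier conversion from probe voltage to raw sap flow density
#'
#' \deqn{J = 118.99\times10^{-6}\,\big((\Delta U^* - \Delta U)/\Delta U\big)^{1.231}}
#' in m s^-1. Records where \eqn{\Delta U > \Delta U^*} (night-time noise
#' crossing the baseline) are clamped to zero and counted rather than
#' treated as errors.
#'
#' @param dU measured voltage difference (mV), must be positive.
#' @param dU_star zero-flow baseline voltage (mV), must be positive.
#' @return list with `J` (m s^-1, NA propagated) and `n_clamped`, the
#'   number of clamped negative-argument records.
#' @export
granier_flux <- function(dU, dU_star) {
  if (any(dU <= 0, na.rm = TRUE)) stop("invalid record: dU must be positive")
  if (any(dU_star <= 0, na.rm = TRUE)) stop("invalid baseline: dU_star must be positive")
  ratio <- (dU_star - dU) / dU
  clamped <- !is.na(ratio) & ratio < 0
  ratio[clamped] <- 0
  J <- sapflow_constants$granier_coef * ratio^sapflow_constants$granier_exp
  list(J = J, n_clamped = sum(clamped))
}

#' Area-weighted whole-tree sap flow from per-probe fluxes
#'
#' Each probe represents one quadrant's sapwood annulus reaching from
#' radius `dbh/2 - bark_depth - sapwood_depth` to `dbh/2 - bark_depth`;
#' the whole-tree flux is the annulus-area-weighted mean of the probe
#' fluxes, dropping probes with missing values timestamp by timestamp.
#'
#' @param flux matrix (timestamps x probes) or vector of per-probe molar
#'   fluxes.
#' @param sapwood_depth per-probe sapwood depth (cm).
#' @param dbh stem diameter at breast height (cm).
#' @param bark_depth bark thickness (cm), default 0.
#' @return numeric vector of whole-tree flux; NA where every probe is
#'   missing.
#' @export
aggregate_tree <- function(flux, sapwood_depth, dbh, bark_depth = 0) {
  if (is.vector(flux)) flux <- matrix(flux, nrow = 1)
  stopifnot(ncol(flux) == length(sapwood_depth), dbh > 0, all(sapwood_depth > 0))
  r_out <- dbh / 2 - bark_depth
  r_in <- pmax(r_out - sapwood_depth, 0)
  w <- r_out^2 - r_in^2  # pi/4 quadrant factor cancels in the weighted mean
  out <- apply(flux, 1L, function(f) {
    ok <- !is.na(f)
    if (!any(ok)) return(NA_real_)
    sum(w[ok] * f[ok]) / sum(w[ok])
  })
  as.numeric(out)
}

#' Average a finer-resolution series onto the 10-min grid
#'
#' Timestamps label the END of each averaging interval: a value stamped
#' `t` is the mean over `(t - dt, t]`.
#'
#' @param timestamp POSIXct timestamps of the fine series.
#' @param value numeric values.
#' @param dt_min target resolution (minutes), default 10.
#' @return data.frame with `timestamp` (interval end) and `value`.
#' @export
resample_10min <- function(timestamp, value, dt_min = 10) {
  sec <- dt_min * 60
  # absolute grid: a value at exactly a grid point belongs to the
  # interval ending there
  bin <- ceiling(as.numeric(timestamp) / sec - 1e-9)
  agg <- tapply(value, bin, mean, na.rm = TRUE)
  ends <- as.POSIXct(as.numeric(names(agg)) * sec,
                     origin = "1970-01-01", tz = attr(timestamp, "tzone") %||% "UTC")
  data.frame(timestamp = ends, value = as.numeric(agg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Container for one tree's aligned sap flow and driver series
#'
#' Holds the complete 10-min grid (needed by the time-lag interpolation,
#' which looks the observation up `chi` minutes ahead of each model row)
#' together with the filtered model rows: rows with `D <= 0` are removed
#' from the likelihood, as the optimal-conductance model has a `1/D`
#' singularity there.
#'
#' @param tree_id label.
#' @param age_group `"young"` or `"old"`.
#' @param height tree height (m).
#' @param dbh diameter at breast height (cm).
#' @param age tree age (years), optional.
#' @param timestamp POSIXct 10-min grid (end-of-interval labels).
#' @param J_obs observed whole-tree sap flow density (mol m^-2 SW s^-1).
#' @param D vapour deficit (mol m^-3).
#' @param I photosynthetic photon flux density (mol m^-2 s^-1).
#' @param Ca CO2 concentration (mol m^-3).
#' @param dt_min grid step (minutes).
#' @return object of class `tree_dataset` with elements `rows` (the
#'   valid model rows), `full` (the complete grid), `n_rows`, and the
#'   metadata fields.
#' @export
tree_dataset <- function(tree_id, age_group, height, dbh, age = NA_real_,
                         timestamp, J_obs, D, I, Ca, dt_min = 10) {
  age_group <- match.arg(age_group, c("young", "old"))
  n <- length(timestamp)
  stopifnot(length(J_obs) == n, length(D) == n, length(I) == n,
            length(Ca) == n)
  if (n > 1) {
    steps <- diff(as.numeric(timestamp))
    if (any(abs(steps - dt_min * 60) > 1e-6)) {
      stop("timestamps of ", tree_id, " are not on a uniform ",
           dt_min, "-min grid")
    }
  }
  full <- data.frame(timestamp = timestamp, J_obs = J_obs, D = D, I = I, Ca = Ca)
  valid <- !is.na(D) & D > 0 & !is.na(I) & !is.na(Ca) & !is.na(J_obs)
  rows <- full[valid, , drop = FALSE]
  if (nrow(rows) == 0L) stop("tree ", tree_id, ": no valid rows after filtering D <= 0")
  structure(list(
    tree_id = tree_id, age_group = age_group, height = height, dbh = dbh,
    age = age, rows = rows, full = full, valid = valid,
    n_rows = nrow(rows), dt_min = dt_min
  ), class = "tree_dataset")
}

#' @export
print.tree_dataset <- function(x, ...) {
  cat(sprintf("<tree_dataset %s (%s): H = %.1f m, DBH = %.1f cm, %d/%d valid rows>\n",
              x$tree_id, x$age_group, x$height, x$dbh, x$n_rows, nrow(x$full)))
  invisible(x)
}

#' Build per-tree model datasets from probe voltages and meteorology
#'
#' Runs the full preprocessing chain: per-probe baseline detection and
#' Granier conversion, molar conversion, quadrant-annulus aggregation to
#' the whole tree, and the join with the drivers (D, I, Ca) on the
#' 10-min grid. Young trees take temperature/humidity from the lower
#' measurement height, old trees from the higher; PPFD and CO2 are
#' shared. Rows with `D <= 0` are excluded from the model rows.
#'
#' @param probes data.frame with columns `tree_id`, `probe_id`,
#'   `timestamp` (POSIXct) and `dU_mV`, long format.
#' @param geometry data.frame with `tree_id`, `probe_id`,
#'   `sapwood_depth_cm` and optionally `azimuth`, `mount_height_cm`.
#' @param meteo either a single meteorology data.frame or
#'   `list(young = ..., old = ...)`, each with columns `timestamp`,
#'   `T_C`, `RH_pct`, `PPFD_mol_m2_s`, `CO2_ppm` at 10-min resolution or
#'   finer (finer series are averaged to 10 min).
#' @param trees data.frame with `tree_id`, `age_group`, `height_m`,
#'   `dbh_cm`, optionally `age_yr` and `bark_depth_cm`.
#' @param ... passed to [detect_baseline()].
#' @return list with `data` (list of [tree_dataset()]) and `qc`
#'   (data.frame of per-tree baseline counts, clamped records and
#'   dropped rows).
#' @export
build_dataset <- function(probes, geometry, meteo, trees, ...) {
  if (is.data.frame(meteo)) meteo <- list(young = meteo, old = meteo)
  met <- lapply(meteo, prepare_meteo)
  out <- list(); qc <- NULL
  for (i in seq_len(nrow(trees))) {
    tr <- trees[i, ]
    m <- met[[as.character(tr$age_group)]]
    pr <- probes[probes$tree_id == tr$tree_id, , drop = FALSE]
    if (nrow(pr) == 0L) stop("no probe data for tree ", tr$tree_id)
    geo <- geometry[geometry$tree_id == tr$tree_id, , drop = FALSE]
    pids <- unique(pr$probe_id)
    flux <- NULL; n_clamped <- 0L; n_baseline <- 0L
    for (p in pids) {
      sub <- pr[pr$probe_id == p, ]
      sub <- sub[order(sub$timestamp), ]
      j <- match(round(as.numeric(sub$timestamp)), round(as.numeric(m$timestamp)))
      if (any(is.na(j))) stop("probe ", p, " timestamps not aligned with meteorology")
      bl <- detect_baseline(sub$dU_mV, m$VPD_pa[j], probe_id = paste(tr$tree_id, p), ...)
      gf <- granier_flux(sub$dU_mV, bl$dU_star)
      n_clamped <- n_clamped + gf$n_clamped
      n_baseline <- n_baseline + sum(bl$baseline)
      col <- rep(NA_real_, length(m$timestamp))
      col[j] <- molar_flux(gf$J)
      flux <- cbind(flux, col)
    }
    depths <- geo$sapwood_depth_cm[match(pids, geo$probe_id)]
    if (any(is.na(depths))) stop("missing sapwood depth for a probe of ", tr$tree_id)
    bark <- if ("bark_depth_cm" %in% names(tr)) tr$bark_depth_cm else 0
    J_tree <- aggregate_tree(flux, depths, tr$dbh_cm, bark)
    keep <- !is.na(J_tree)
    if (!any(keep & m$D > 0)) stop("empty join for tree ", tr$tree_id)
    ds <- tree_dataset(
      tree_id = tr$tree_id, age_group = as.character(tr$age_group),
      height = tr$height_m, dbh = tr$dbh_cm,
      age = if ("age_yr" %in% names(tr)) tr$age_yr else NA_real_,
      timestamp = m$timestamp, J_obs = J_tree, D = m$D, I = m$I, Ca = m$Ca
    )
    out[[tr$tree_id]] <- ds
    qc <- rbind(qc, data.frame(
      tree_id = tr$tree_id, n_baseline_points = n_baseline,
      n_clamped = n_clamped, n_rows = ds$n_rows,
      n_dropped = nrow(ds$full) - ds$n_rows
    ))
  }
  list(data = out, qc = qc)
}

# 10-min averaging + derived driver columns for one meteorology table
prepare_meteo <- function(m) {
  need <- c("timestamp", "T_C", "RH_pct", "PPFD_mol_m2_s", "CO2_ppm")
  stopifnot(all(need %in% names(m)))
  cols <- lapply(need[-1], function(v) resample_10min(m$timestamp, m[[v]]))
  ts <- cols[[1]]$timestamp
  T_C <- cols[[1]]$value; RH <- cols[[2]]$value
  I <- cols[[3]]$value; ppm <- cols[[4]]$value
  vp <- vpd_pa(T_C, RH)
  data.frame(timestamp = ts, T_C = T_C, RH_pct = RH, I = I,
             VPD_pa = vp, D = vpd_molar(vp, T_C),
             Ca = co2_molar(ppm, T_C))
}
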
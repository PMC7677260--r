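#' Root-mean-square error of model residuals
#'
#' `rmse` is \eqn{\sqrt{\sum\varepsilon^2/N}}; `rmse_pct` normalises by
#' the mean observed sap flow, \eqn{100\,RMSE/\bar J^{(O)}}.
#'
#' @param errors residual vector (non-empty).
#' @param J_obs observed values with positive mean (for `rmse_pct`).
#' @return scalar RMSE (same units as the residuals) or percent.
#' @export
rmse <- function(errors) {
  if (length(errors) == 0L) stop("empty residual vector")
  sqrt(mean(errors^2))
}

#' @rdname rmse
#' @export
rmse_pct <- function(errors, J_obs) {
  m <- mean(J_obs)
  if (!is.finite(m) || m <= 0) stop("mean of J_obs must be positive")
  100 * rmse(errors) / m
}

# draw Laplace(0, s) variates
rlaplace <- function(n, scale) {
  u <- stats::runif(n) - 0.5
  -scale * sign(u) * log1p(-2 * abs(u))
}

#' Parametric and predictive uncertainty bands
#'
#' For each tree and timestamp, the parametric band is the pointwise
#' 95% interval of the modelled sap flow over the posterior draws; the
#' predictive band adds one Laplace noise realisation per draw (young:
#' heteroscedastic scale; old: constant scale) and truncates at zero,
#' since negative sap flow lacks physical meaning. The measurement
#' component is the region between the two bands. Finite-sample quantile
#' crossings are resolved by nesting the parametric band inside the
#' predictive band.
#'
#' @param data list of [tree_dataset()] objects.
#' @param draws matrix of posterior parameter draws
#'   ([posterior_draws()]), at least 100 rows.
#' @param Ca scalar CO2 concentration or `NULL` for per-row values.
#' @param seed RNG seed for the noise realisations.
#' @param level interval coverage, default 0.95.
#' @return named list of per-tree data.frames with columns `timestamp`,
#'   `param_lo`, `param_hi`, `pred_lo`, `pred_hi`.
#' @export
predictive_bands <- function(data, draws, Ca = NULL, seed = 1, level = 0.95) {
  if (nrow(draws) < 100) stop("need at least 100 posterior draws")
  set.seed(seed)
  a2 <- (1 - level) / 2
  ids <- tree_ids_by_group(data)
  out <- list()
  for (d in data) {
    nr <- d$n_rows
    ca <- if (is.null(Ca)) d$rows$Ca else Ca
    Jm <- matrix(NA_real_, nrow(draws), nr)
    S <- matrix(NA_real_, nrow(draws), nr)
    for (k in seq_len(nrow(draws))) {
      th <- draws[k, ]
      sfx <- if (d$age_group == "young") "Y" else "O"
      p <- stomatal_params(th[[paste0("lambda_", sfx)]],
                           th[[paste0("iota_", sfx)]],
                           th[[paste0("gamma_", sfx)]])
      j <- modeled_sapflow(d$rows$D, d$rows$I, p, th[[paste0("rho_", d$tree_id)]], ca)
      Jm[k, ] <- j
      S[k, ] <- if (d$age_group == "young") {
        laplace_scale_young(j, th[[paste0("a_", d$tree_id)]],
                            th[[paste0("b_", d$tree_id)]], th[["c_Y"]])
      } else rep(th[["c_O"]], nr)
    }
    pred <- pmax(Jm + matrix(rlaplace(length(S), as.vector(S)), nrow(draws), nr), 0)
    qs <- function(m) apply(m, 2, stats::quantile, probs = c(a2, 1 - a2), names = FALSE)
    qp <- qs(Jm); qq <- qs(pred)
    out[[d$tree_id]] <- data.frame(
      timestamp = d$rows$timestamp,
      param_lo = qp[1, ], param_hi = qp[2, ],
      pred_lo = pmin(qq[1, ], qp[1, ]), pred_hi = pmax(qq[2, ], qp[2, ])
    )
  }
  out
}

# unit-box posterior-mode refit used by the cross-validation
optimise_mode <- function(lp, theta0, lower, upper, free, maxit = 300) {
  width <- upper - lower
  to_u <- function(th) (th - lower) / width
  to_t <- function(u) lower + u * width
  u0 <- to_u(theta0)
  f <- function(ufree) {
    u <- u0; u[free] <- ufree
    v <- lp(to_t(u))
    if (!is.finite(v)) 1e12 else -v
  }
  eps <- 1e-9
  res <- stats::optim(pmin(pmax(u0[free], eps), 1 - eps), f, method = "L-BFGS-B",
                      lower = eps, upper = 1 - eps,
                      control = list(maxit = maxit, factr = 1e4,
                                     ndeps = rep(1e-7, sum(free))))
  u <- u0; u[free] <- res$par
  list(theta = to_t(u), value = -res$value)
}

#' Leave-one-day-out cross-validation of the hierarchical model
#'
#' Days 1-8 of the series are removed in turn; the model is refitted on
#' the remaining data with either both `iota` or both `gamma`
#' parameters pinned to the full-data MAP (the two parameters are
#' strongly correlated through the light response curve), and the
#' removed day is simulated from the fold estimate. Fold refits are
#' posterior-mode searches (two-stage bounded quasi-Newton in unit-box
#' coordinates, nuisance scale/hyper parameters first, then all free
#' parameters jointly) seeded at the full-data MAP; a full MCMC refit
#' per fold is available via `method = "mcmc"`.
#'
#' @param data list of [tree_dataset()] objects with >= 8 calendar days.
#' @param priors a [prior_spec()] (default from the data).
#' @param mode `"fix_iota"` or `"fix_gamma"`.
#' @param theta_map_full named full-data MAP vector.
#' @param Ca scalar CO2 or `NULL`.
#' @param seed RNG seed (used by `method = "mcmc"`).
#' @param method `"optim"` (default) or `"mcmc"`.
#' @param n_iter MCMC iterations per fold when `method = "mcmc"`.
#' @return list with `summary` (data.frame: fold, rmse_holdout,
#'   n_holdout) and `estimates` (list of fold parameter vectors).
#' @export
cross_validate <- function(data, priors = NULL, mode = c("fix_iota", "fix_gamma"),
                           theta_map_full, Ca = NULL, seed = 1,
                           method = c("optim", "mcmc"), n_iter = 4000) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  ids <- tree_ids_by_group(data)
  if (is.null(priors)) priors <- prior_spec(ids$young, ids$old)
  nm <- param_names(ids$young, ids$old)
  pp <- priors[match(nm, priors$name), ]
  theta0 <- theta_map_full[nm]
  days <- sort(unique(as.Date(data[[1]]$full$timestamp)))
  if (length(days) < 8) stop("cross-validation needs at least 8 calendar days")
  days <- days[1:8]
  fixed_names <- if (mode == "fix_iota") c("iota_Y", "iota_O") else c("gamma_Y", "gamma_O")
  nuisance <- grepl("^(a_|b_|c_|mu_|sigma_)", nm)
  res <- NULL; est <- list()
  for (fold in seq_along(days)) {
    day <- days[fold]
    train <- lapply(data, mask_day, day = day)
    lp <- make_log_posterior(train, priors, Ca = Ca)
    free_all <- !(nm %in% fixed_names)
    if (method == "optim") {
      s1 <- optimise_mode(lp, theta0, pp$lower, pp$upper, free = nuisance & free_all)
      s2 <- optimise_mode(lp, s1$theta, pp$lower, pp$upper, free = free_all)
      theta_fold <- s2$theta
    } else {
      ch <- run_sampler(lp, pp$lower, pp$upper, n_iter = n_iter,
                        seed = seed + fold, param_names = nm)
      theta_fold <- map_estimate(ch)
    }
    names(theta_fold) <- nm
    # held-out residuals: only the removed day's rows
    hold <- lapply(data, keep_day, day = day)
    hold <- hold[!vapply(hold, is.null, logical(1))]
    if (length(hold) < length(data)) {
      warning("fold ", fold, ": some trees have no data on ", format(day))
    }
    eps <- unlist(sapflow_residuals(hold, theta_fold, Ca = Ca))
    res <- rbind(res, data.frame(fold = fold, day = day,
                                 rmse_holdout = rmse(eps),
                                 n_holdout = length(eps)))
    est[[fold]] <- theta_fold
  }
  list(summary = res, estimates = est, mode = mode, method = method)
}

# drop one calendar day from the model rows (observation grid kept for lags)
mask_day <- function(d, day) {
  drop <- as.Date(d$full$timestamp) == day
  d$valid <- d$valid & !drop
  d$rows <- d$full[d$valid, , drop = FALSE]
  d$n_rows <- nrow(d$rows)
  d
}

# keep only one calendar day's model rows
keep_day <- function(d, day) {
  keep <- as.Date(d$full$timestamp) == day
  d$valid <- d$valid & keep
  if (!any(d$valid)) return(NULL)
  d$rows <- d$full[d$valid, , drop = FALSE]
  d$n_rows <- nrow(d$rows)
  d
}

#' Regression of the leaf-sapwood area ratio on tree height
#'
#' Ordinary least squares of \eqn{A_L\!:\!A_{SW}} (m^2 cm^-2, i.e.
#' `rho` x 1e-4) on height (m), with Cook's distances computed on the
#' all-points fit; at most the single most influential point with
#' Cook's D above `cooks_threshold` is excluded for a second fit.
#'
#' @param rho per-tree leaf-sapwood area ratios (m^2 m^-2, native
#'   units), named by tree.
#' @param H per-tree heights (m).
#' @param cooks_threshold exclusion threshold, default 0.5.
#' @return list with `all` and `excluded` fits (each: slope, intercept,
#'   r_squared, n), `cooks` (named), `excluded_point` (label or NA).
#' @export
rho_height_regression <- function(rho, H, cooks_threshold = 0.5) {
  stopifnot(length(rho) == length(H), length(rho) >= 3)
  y <- rho * 1e-4
  fit <- stats::lm(y ~ H)
  cooks <- stats::cooks.distance(fit)
  names(cooks) <- names(rho) %||% seq_along(rho)
  summ <- function(f, n) list(slope = unname(stats::coef(f)[2]),
                              intercept = unname(stats::coef(f)[1]),
                              r_squared = summary(f)$r.squared, n = n)
  worst <- which.max(cooks)
  out <- list(all = summ(fit, length(y)), cooks = cooks,
              excluded_point = NA_character_, excluded = NULL)
  if (cooks[worst] > cooks_threshold) {
    f2 <- stats::lm(y[-worst] ~ H[-worst])
    out$excluded <- summ(f2, length(y) - 1L)
    out$excluded_point <- names(cooks)[worst]
  }
  out
}

#' Through-origin regression of the time lag on tree height
#'
#' Least-squares line through the origin,
#' \eqn{slope = \sum H\chi / \sum H^2}; the coefficient of
#' determination uses the CENTRED total sum of squares
#' (\eqn{R^2 = 1 - SS_{res}/\sum(\chi - \bar\chi)^2}), the convention
#' under which the fit to the published tree table reproduces the
#' published value.
#'
#' @param chi per-tree time lags (minutes).
#' @param H per-tree heights (m).
#' @return list with `slope` (min m^-1), `r_squared`, `n`.
#' @export
chi_height_regression <- function(chi, H) {
  stopifnot(length(chi) == length(H), length(chi) >= 2)
  slope <- sum(H * chi) / sum(H^2)
  ss_res <- sum((chi - slope * H)^2)
  ss_tot <- sum((chi - mean(chi))^2)
  list(slope = slope, r_squared = 1 - ss_res / ss_tot, n = length(chi))
}

#' Standardise a slope by the sample maxima
#'
#' Converts a raw slope of y on x into the slope of y/max(y) on
#' x/max(x), i.e. `slope * max(x) / max(y)`.
#'
#' @param slope raw regression slope.
#' @param y_values,x_values the regression inputs (y on the slope's own
#'   scale, e.g. A_L:A_SW in m^2 cm^-2).
#' @return dimensionless standardised slope.
#' @export
standardized_slope <- function(slope, y_values, x_values) {
  stopifnot(length(y_values) >= 1, length(x_values) >= 1)
  slope * max(x_values) / max(y_values)
}

#' Observed-versus-modelled regression
#'
#' OLS of the lag-matched observations on the modelled sap flow across
#' all trees and timepoints; slope near 1 and high R^2 indicate an
#' unbiased fit.
#'
#' @param J_mod modelled values.
#' @param J_obs lag-matched observed values.
#' @return list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
obs_vs_mod_regression <- function(J_mod, J_obs) {
  stopifnot(length(J_mod) == length(J_obs))
  fit <- stats::lm(J_obs ~ J_mod)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared, n = length(J_mod))
}

#' Fitted sap flow and lag-matched observations at a parameter vector
#'
#' Convenience wrapper returning, per tree, the modelled series at
#' `theta` and the lag-matched observations over the rows where both
#' exist (used for the observed-versus-modelled fit and RMSE).
#'
#' @inheritParams sapflow_residuals
#' @return data.frame with `tree_id`, `J_mod`, `J_obs_lagged`.
#' @export
fitted_sapflow <- function(data, theta, Ca = NULL) {
  ids <- tree_ids_by_group(data)
  th <- split_theta(theta, ids$young, ids$old)
  out <- NULL
  for (d in data) {
    p <- if (d$age_group == "young") th$young else th$old
    ca <- if (is.null(Ca)) d$rows$Ca else Ca
    Jm <- modeled_sapflow(d$rows$D, d$rows$I, p, th$rho[[d$tree_id]], ca)
    lag <- lagged_observation(d$full$J_obs, th$chi[[d$tree_id]],
                              at = which(d$valid), dt_min = d$dt_min)
    ok <- !is.na(lag)
    out <- rbind(out, data.frame(tree_id = d$tree_id,
                                 J_mod = Jm[ok], J_obs_lagged = lag[ok]))
  }
  out
}
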
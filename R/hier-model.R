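#' Canonical parameter names for a given set of trees
#'
#' The full parameter vector stacks, in order: the age-group stomatal
#' parameters (lambda, iota, gamma for young and old), per-tree
#' leaf-sapwood ratios `rho_*`, per-tree time lags `chi_*` (minutes),
#' the young-tree heteroscedastic error-curve parameters `a_*` and
#' `b_*`, the baseline Laplace scales `c_Y`, `c_O`, and the
#' heavy-tailed-prior hyperparameters `mu_Y`, `mu_O`, `sigma_Y`,
#' `sigma_O`. For 5 young and 6 old trees this is the 44-parameter
#' vector of the full model.
#'
#' @param young_ids,old_ids character vectors of tree labels.
#' @return character vector of parameter names.
#' @export
param_names <- function(young_ids, old_ids) {
  c("lambda_Y", "lambda_O", "iota_Y", "iota_O", "gamma_Y", "gamma_O",
    paste0("rho_", c(young_ids, old_ids)),
    paste0("chi_", c(young_ids, old_ids)),
    paste0("a_", young_ids), paste0("b_", young_ids),
    "c_Y", "c_O", "mu_Y", "mu_O", "sigma_Y", "sigma_O")
}

#' Parameter counts of the hierarchical model
#'
#' Total count: 6 age-group stomatal parameters + 2 per tree (rho, chi)
#' + 2 per young tree (a, b) + 6 distribution parameters (c, mu, sigma
#' per age group). The direct-simulation subset (the parameters entering
#' the sap flow prediction itself) is the first two groups.
#'
#' @param n_young,n_old numbers of young and old trees (>= 1).
#' @return list with `total` and `direct`.
#' @export
count_parameters <- function(n_young, n_old) {
  stopifnot(n_young >= 1, n_old >= 1)
  n_young <- as.integer(n_young); n_old <- as.integer(n_old)
  direct <- 3L * 2L + 2L * (n_young + n_old)
  list(total = direct + 2L * n_young + 3L * 2L, direct = direct)
}

#' Prior specification (bounds) for the hierarchical model
#'
#' Uniform boxes for every parameter; `rho` additionally carries the
#' heavy-tailed hierarchical density inside its box (see [log_prior()]).
#' Defaults: lambda in \[0.5e-3, 6.0e-3\], iota in \[0.1, 1.2\], gamma in
#' \[1.6e-3, 5.0e-3\]; rho in \[3000, 6500\] (young) / \[2500, 6000\]
#' (old); chi in \[10, 180\] minutes (the literature lag range of 1-18
#' ten-minute measurement intervals); a in \[1e-3, 2\], b in \[1e-2, 5\],
#' c in \[1e-3, 5\] (mol m^-2 SW s^-1); mu within the corresponding rho
#' box; sigma in \[10, 2000\].
#'
#' @param young_ids,old_ids tree labels.
#' @param rho_young,rho_old,chi,lambda,iota,gamma,a,b,c_scale,sigma
#'   length-2 `(lower, upper)` overrides.
#' @return object of class `prior_spec`: data.frame with `name`,
#'   `lower`, `upper`, plus attributes identifying the rho block.
#' @export
prior_spec <- function(young_ids, old_ids,
                       rho_young = c(3000, 6500), rho_old = c(2500, 6000),
                       chi = c(10, 180),
                       lambda = c(0.5e-3, 6.0e-3), iota = c(0.1, 1.2),
                       gamma = c(1.6e-3, 5.0e-3),
                       a = c(1e-3, 2), b = c(1e-2, 5), c_scale = c(1e-3, 5),
                       sigma = c(10, 2000)) {
  nm <- param_names(young_ids, old_ids)
  nY <- length(young_ids); nO <- length(old_ids)
  lower <- c(lambda[1], lambda[1], iota[1], iota[1], gamma[1], gamma[1],
             rep(rho_young[1], nY), rep(rho_old[1], nO),
             rep(chi[1], nY + nO),
             rep(a[1], nY), rep(b[1], nY),
             c_scale[1], c_scale[1], rho_young[1], rho_old[1],
             sigma[1], sigma[1])
  upper <- c(lambda[2], lambda[2], iota[2], iota[2], gamma[2], gamma[2],
             rep(rho_young[2], nY), rep(rho_old[2], nO),
             rep(chi[2], nY + nO),
             rep(a[2], nY), rep(b[2], nY),
             c_scale[2], c_scale[2], rho_young[2], rho_old[2],
             sigma[2], sigma[2])
  out <- data.frame(name = nm, lower = lower, upper = upper)
  stopifnot(all(out$lower < out$upper))
  attr(out, "young_ids") <- young_ids
  attr(out, "old_ids") <- old_ids
  class(out) <- c("prior_spec", "data.frame")
  out
}

#' Heavy-tailed Gaussian log-density (Sivia-Skilling form)
#'
#' \deqn{p(\rho) = \frac{1}{\sigma\sqrt{2\pi}}\,
#'   \frac{1 - e^{-z^2/2}}{z^2},\qquad z = (\rho-\mu)/\sigma,}
#' a robust unimodal density with Cauchy-like \eqn{1/z^2} tails; the
#' removable singularity at z = 0 takes its analytic limit value 1/2 for
#' the bracketed factor. Computed with `expm1` so the limit is reached
#' continuously.
#'
#' @param rho value(s).
#' @param mu location.
#' @param sigma scale (> 0).
#' @return log-density.
#' @export
heavy_tailed_logpdf <- function(rho, mu, sigma) {
  stopifnot(sigma > 0)
  z2 <- ((rho - mu) / sigma)^2
  frac <- ifelse(z2 == 0, 0.5, -expm1(-z2 / 2) / z2)
  log(frac) - log(sigma * sqrt(2 * pi))
}

#' Observed sap flow interpolated at a lagged time
#'
#' The basal sap flow trails crown transpiration by a tree-specific lag
#' `chi` (minutes); the observation matched to model time `t` is taken
#' at `t + chi`, linearly interpolated between the two bracketing grid
#' points: with offsets `t0 <= chi <= t1` (`t1 - t0 = 10` min), the
#' standard proximity weighting is
#' `((t1 - chi) J(t + t0) + (chi - t0) J(t + t1)) / 10`. The variant
#' with the weights attached the other way round is available as
#' `interp = "printed"`.
#'
#' @param J_obs observed series on the uniform grid.
#' @param chi time lag (minutes).
#' @param at integer indices of the model times within the grid
#'   (default all).
#' @param dt_min grid step (minutes).
#' @param interp `"standard"` (proximity weights) or `"printed"`.
#' @return numeric vector of lagged observations; NA where `t + chi`
#'   leaves the observed span (such rows are excluded from the
#'   likelihood).
#' @export
lagged_observation <- function(J_obs, chi, at = seq_along(J_obs), dt_min = 10,
                               interp = c("standard", "printed")) {
  interp <- match.arg(interp)
  n <- length(J_obs)
  k0 <- floor(chi / dt_min + 1e-12)
  f <- chi / dt_min - k0
  j0 <- at + k0
  out <- rep(NA_real_, length(at))
  if (f < 1e-12) {
    ok <- j0 >= 1 & j0 <= n
    out[ok] <- J_obs[j0[ok]]
  } else {
    j1 <- j0 + 1L
    ok <- j0 >= 1 & j1 <= n
    w0 <- if (interp == "standard") 1 - f else f
    out[ok] <- w0 * J_obs[j0[ok]] + (1 - w0) * J_obs[j1[ok]]
  }
  out
}

#' Laplace log-density with location zero
#'
#' \eqn{\log p(\varepsilon; s) = -\log(2s) - |\varepsilon|/s}.
#'
#' @param eps residual(s).
#' @param scale Laplace scale s (> 0).
#' @return log-density.
#' @export
laplace_logdens <- function(eps, scale) {
  stopifnot(all(scale > 0))
  -log(2 * scale) - abs(eps) / scale
}

#' Heteroscedastic Laplace scale for young trees
#'
#' Saturating scale curve
#' \eqn{s = c_Y + a b J^{(M)} / (a J^{(M)} + b)} with initial slope `a`
#' and asymptote `b` above the baseline scale `c_Y`: measurement error
#' in the open young stand grows with the modelled flux (direct sunlight
#' on the probes) but saturates.
#'
#' @param J_mod modelled sap flow density (>= 0).
#' @param a initial slope (dimensionless), > 0.
#' @param b asymptote (mol m^-2 SW s^-1), > 0.
#' @param c_Y baseline scale (mol m^-2 SW s^-1), > 0.
#' @return Laplace scale (mol m^-2 SW s^-1).
#' @export
laplace_scale_young <- function(J_mod, a, b, c_Y) {
  stopifnot(a > 0, b > 0, c_Y > 0)
  c_Y + a * b * J_mod / (a * J_mod + b)
}

# split a named theta vector into the blocks the model consumes
split_theta <- function(theta, young_ids, old_ids) {
  g <- function(nm) unname(theta[nm])
  list(
    young = stomatal_params(g("lambda_Y"), g("iota_Y"), g("gamma_Y")),
    old = stomatal_params(g("lambda_O"), g("iota_O"), g("gamma_O")),
    rho = stats::setNames(g(paste0("rho_", c(young_ids, old_ids))), c(young_ids, old_ids)),
    chi = stats::setNames(g(paste0("chi_", c(young_ids, old_ids))), c(young_ids, old_ids)),
    a = stats::setNames(g(paste0("a_", young_ids)), young_ids),
    b = stats::setNames(g(paste0("b_", young_ids)), young_ids),
    c_Y = g("c_Y"), c_O = g("c_O"),
    mu = c(young = g("mu_Y"), old = g("mu_O")),
    sigma = c(young = g("sigma_Y"), old = g("sigma_O"))
  )
}

#' Tree labels of a dataset list, split by age group
#'
#' @param data list of [tree_dataset()] objects.
#' @return list with character vectors `young` and `old`.
#' @export
tree_ids_by_group <- function(data) {
  ag <- vapply(data, function(d) d$age_group, character(1))
  list(young = vapply(data[ag == "young"], function(d) d$tree_id, character(1)),
       old = vapply(data[ag == "old"], function(d) d$tree_id, character(1)))
}

#' Model-observation residuals with the time lag considered
#'
#' \eqn{\varepsilon_{m,t} = J^{(O)}(t + \chi_m) - J^{(M)}_{m,t}} over
#' each tree's valid model rows; lag lookups that leave the observed
#' span are dropped (count reported as attribute `n_excluded`).
#'
#' @param data list of [tree_dataset()] objects.
#' @param theta named parameter vector (see [param_names()]).
#' @param Ca CO2 concentration (mol m^-3); if `NULL`, taken per row
#'   from the datasets.
#' @param interp interpolation convention, see [lagged_observation()].
#' @return named list of residual vectors, one per tree.
#' @export
sapflow_residuals <- function(data, theta, Ca = NULL,
                              interp = c("standard", "printed")) {
  interp <- match.arg(interp)
  ids <- tree_ids_by_group(data)
  th <- split_theta(theta, ids$young, ids$old)
  out <- list(); n_excl <- 0L
  for (d in data) {
    p <- if (d$age_group == "young") th$young else th$old
    ca <- if (is.null(Ca)) d$rows$Ca else Ca
    Jm <- modeled_sapflow(d$rows$D, d$rows$I, p, th$rho[[d$tree_id]], ca)
    at <- which(d$valid)
    lag <- lagged_observation(d$full$J_obs, th$chi[[d$tree_id]], at = at,
                              dt_min = d$dt_min, interp = interp)
    ok <- !is.na(lag)
    n_excl <- n_excl + sum(!ok)
    out[[d$tree_id]] <- lag[ok] - Jm[ok]
  }
  attr(out, "n_excluded") <- n_excl
  out
}

#' Log-likelihood of the time-lagged Laplace error model
#'
#' Young-tree residuals follow a zero-centred Laplace distribution with
#' the heteroscedastic scale of [laplace_scale_young()]; old-tree
#' residuals a constant scale `c_O`. The log-density of one residual is
#' \eqn{-\log(2s) - |\varepsilon|/s}.
#'
#' @inheritParams sapflow_residuals
#' @return scalar log-likelihood (`-Inf` if any residual is
#'   non-finite).
#' @export
log_likelihood <- function(data, theta, Ca = NULL,
                           interp = c("standard", "printed")) {
  lp <- make_log_posterior(data, priors = NULL, Ca = Ca,
                           interp = match.arg(interp))
  attr(lp, "loglik")(theta)
}

#' Log-prior of the hierarchical model
#'
#' `-Inf` outside any uniform bound; inside the box, the sum of the
#' heavy-tailed log-densities of the per-tree `rho` given the age-group
#' hyperparameters (`mu`, `sigma`). Uniform factors contribute only a
#' constant and are omitted.
#'
#' @param theta named parameter vector.
#' @param priors a [prior_spec()].
#' @return scalar log-prior.
#' @export
log_prior <- function(theta, priors) {
  theta <- theta[priors$name]
  if (any(is.na(theta)) || any(theta < priors$lower) || any(theta > priors$upper)) {
    return(-Inf)
  }
  yid <- attr(priors, "young_ids"); oid <- attr(priors, "old_ids")
  sum(heavy_tailed_logpdf(theta[paste0("rho_", yid)], theta[["mu_Y"]], theta[["sigma_Y"]])) +
    sum(heavy_tailed_logpdf(theta[paste0("rho_", oid)], theta[["mu_O"]], theta[["sigma_O"]]))
}

#' Joint log-posterior (unnormalised)
#'
#' @inheritParams sapflow_residuals
#' @param priors a [prior_spec()].
#' @return scalar log-posterior, `log_likelihood + log_prior`.
#' @export
log_posterior <- function(theta, data, priors, Ca = NULL,
                          interp = c("standard", "printed")) {
  make_log_posterior(data, priors, Ca = Ca, interp = match.arg(interp))(theta)
}

#' Compile a fast log-posterior closure
#'
#' Precomputes per-tree driver vectors and lag index maps so repeated
#' evaluation inside the sampler is cheap. The returned function takes a
#' named (or canonically ordered) parameter vector and returns the
#' unnormalised log-posterior; a likelihood-only evaluator is attached
#' as attribute `"loglik"`.
#'
#' @inheritParams sapflow_residuals
#' @param priors a [prior_spec()] or `NULL` (likelihood only).
#' @return function(theta) -> log-posterior.
#' @export
make_log_posterior <- function(data, priors, Ca = NULL,
                               interp = c("standard", "printed")) {
  interp <- match.arg(interp)
  ids <- tree_ids_by_group(data)
  nm <- param_names(ids$young, ids$old)
  idx <- stats::setNames(seq_along(nm), nm)
  # trees sharing identical driver vectors reuse one transpiration vector
  drv_key <- vapply(data, function(d) {
    ca <- if (is.null(Ca)) d$rows$Ca else Ca
    paste(d$age_group, digest_num(d$rows$D), digest_num(d$rows$I), digest_num(ca))
  }, character(1))
  drv_grp <- match(drv_key, unique(drv_key))
  pre <- lapply(seq_along(data), function(k) {
    d <- data[[k]]
    young <- d$age_group == "young"
    sfx <- if (young) "Y" else "O"
    list(id = d$tree_id, young = young,
         D = d$rows$D, I = d$rows$I,
         ca = if (is.null(Ca)) d$rows$Ca else rep(Ca, d$n_rows),
         Jfull = d$full$J_obs, nfull = nrow(d$full),
         at = which(d$valid), dt = d$dt_min,
         grp = drv_grp[k] - 1L,  # 0-based for the C++ kernel
         i_lambda = idx[[paste0("lambda_", sfx)]] - 1L,
         i_iota = idx[[paste0("iota_", sfx)]] - 1L,
         i_gamma = idx[[paste0("gamma_", sfx)]] - 1L,
         i_c = idx[[paste0("c_", sfx)]] - 1L,
         i_rho = idx[[paste0("rho_", d$tree_id)]] - 1L,
         i_chi = idx[[paste0("chi_", d$tree_id)]] - 1L,
         i_a = if (young) idx[[paste0("a_", d$tree_id)]] - 1L else 0L,
         i_b = if (young) idx[[paste0("b_", d$tree_id)]] - 1L else 0L)
  })
  n_groups <- max(drv_grp)
  lower <- NULL; upper <- NULL
  i_rho_Y <- idx[paste0("rho_", ids$young)]
  i_rho_O <- idx[paste0("rho_", ids$old)]
  if (!is.null(priors)) {
    pp <- priors[match(nm, priors$name), ]
    lower <- pp$lower; upper <- pp$upper
  }
  dptr <- sapflow_build_data_cpp(pre, n_groups, interp == "printed")
  loglik <- function(theta) {
    if (!is.null(names(theta))) theta <- theta[nm]
    sapflow_loglik_ptr_cpp(unname(theta), dptr)
  }
  f <- function(theta) {
    if (!is.null(names(theta))) theta <- theta[nm]
    theta <- unname(theta)
    if (!is.null(lower) &&
        (any(is.na(theta)) || any(theta < lower) || any(theta > upper))) {
      return(-Inf)
    }
    lp <- sum(heavy_tailed_logpdf(theta[i_rho_Y], theta[idx[["mu_Y"]]],
                                  theta[idx[["sigma_Y"]]])) +
      sum(heavy_tailed_logpdf(theta[i_rho_O], theta[idx[["mu_O"]]],
                              theta[idx[["sigma_O"]]]))
    lp + loglik(theta)
  }
  attr(f, "loglik") <- loglik
  attr(f, "param_names") <- nm
  f
}

# cheap structural fingerprint of a numeric vector (for driver sharing)
digest_num <- function(x) {
  paste(length(x), format(sum(x), digits = 17), format(sum(x * seq_along(x)), digits = 17))
}
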
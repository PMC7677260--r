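#' Parameters of the optimal stomatal-conductance model
#'
#' @param lambda marginal carbon gain per unit water cost
#'   (mol CO2 mol^-1 H2O).
#' @param iota initial slope of the light (PPFD) response curve
#'   (m^3 mol^-1).
#' @param gamma saturation level of the light response curve (m s^-1).
#' @return object of class `stomatal_params`.
#' @export
stomatal_params <- function(lambda, iota, gamma) {
  stopifnot(lambda > 0, iota > 0, gamma > 0)
  structure(list(lambda = lambda, iota = iota, gamma = gamma),
            class = "stomatal_params")
}

#' Optimal steady-state stomatal conductance
#'
#' The conductance that maximises carbon gain at a fixed marginal water
#' cost `lambda`, modulated by a saturating light response:
#' \deqn{g = 1.6\Big(\sqrt{C_a/(1.6\lambda D)} - 1\Big)\,
#'   \frac{\iota\gamma I}{\iota I + \gamma}}
#' Negative values (supercritical vapour deficit,
#' \eqn{D > C_a/(1.6\lambda)}) are clipped to zero; no minimum
#' (cuticular) conductance is applied.
#'
#' @param D vapour deficit (mol m^-3), strictly positive.
#' @param I PPFD (mol m^-2 s^-1), non-negative.
#' @param p a [stomatal_params()] object (or list with `lambda`, `iota`,
#'   `gamma`).
#' @param Ca CO2 concentration (mol m^-3).
#' @param sqrt_form use the square-root form of the CO2 term (default);
#'   `FALSE` selects the non-square-root variant for comparison only.
#' @return stomatal conductance g (m s^-1).
#' @export
conductance <- function(D, I, p, Ca, sqrt_form = TRUE) {
  if (any(D <= 0)) stop("vapour deficit D must be strictly positive")
  if (any(I < 0)) stop("PPFD must be non-negative")
  stopifnot(Ca > 0)
  term <- Ca / (1.6 * p$lambda * D)
  u <- if (sqrt_form) sqrt(term) else term
  light <- p$iota * p$gamma * I / (p$iota * I + p$gamma)
  pmax(1.6 * (u - 1) * light, 0)
}

#' Transpiration rate per unit leaf area
#'
#' \eqn{E = g D}, the mass-transfer form of leaf-level transpiration.
#'
#' @inheritParams conductance
#' @return E (mol m^-2 leaf s^-1).
#' @export
transpiration <- function(D, I, p, Ca, sqrt_form = TRUE) {
  conductance(D, I, p, Ca, sqrt_form) * D
}

#' Modelled whole-tree sap flow density
#'
#' Under the mass-balance assumption (sap flow through the sapwood over
#' the study period equals transpiration through the leaves), the
#' all-sided leaf-to-sapwood area ratio `rho` converts leaf-area
#' transpiration to a sapwood-area flux: \eqn{J^{(M)} = \rho E}.
#'
#' @inheritParams conductance
#' @param rho leaf-to-sapwood area ratio (m^2 leaf m^-2 sapwood).
#' @return J (mol m^-2 SW s^-1).
#' @export
modeled_sapflow <- function(D, I, p, rho, Ca, sqrt_form = TRUE) {
  rho * transpiration(D, I, p, Ca, sqrt_form)
}

#' Partial derivatives of conductance with respect to its drivers
#'
#' Closed forms, with \eqn{u = \sqrt{C_a/(1.6\lambda D)}} and
#' \eqn{f(I) = \iota\gamma I/(\iota I+\gamma)}:
#' \eqn{\partial g/\partial D = -1.6 f(I)\, u / (2D)} and
#' \eqn{\partial g/\partial I = 1.6 (u-1)\,\iota\gamma^2/(\iota I+\gamma)^2}.
#'
#' @inheritParams conductance
#' @return derivative of g with respect to D (resp. I).
#' @export
dg_dD <- function(D, I, p, Ca) {
  u <- sqrt(Ca / (1.6 * p$lambda * D))
  light <- p$iota * p$gamma * I / (p$iota * I + p$gamma)
  -1.6 * light * u / (2 * D)
}

#' @rdname dg_dD
#' @export
dg_dI <- function(D, I, p, Ca) {
  u <- sqrt(Ca / (1.6 * p$lambda * D))
  1.6 * (u - 1) * p$iota * p$gamma^2 / (p$iota * I + p$gamma)^2
}

#' Relative sensitivity of conductance to vapour deficit and light
#'
#' Control-coefficient style sensitivities
#' \eqn{C^g_D = (\partial g/\partial D)(D/g) = 1/(2\sqrt{1.6\lambda D/C_a} - 2)}
#' and
#' \eqn{C^g_I = (\partial g/\partial I)(I/g) = \gamma/(\iota I + \gamma)}.
#' `rel_sens_D` is undefined (signalled) where \eqn{1.6\lambda D = C_a}.
#'
#' @param D vapour deficit (mol m^-3), strictly positive.
#' @param I PPFD (mol m^-2 s^-1), non-negative.
#' @param p stomatal parameters.
#' @param Ca CO2 concentration (mol m^-3).
#' @return dimensionless sensitivity coefficient.
#' @export
rel_sens_D <- function(D, p, Ca) {
  if (any(D <= 0)) stop("D must be strictly positive")
  v <- sqrt(1.6 * p$lambda * D / Ca)
  if (any(abs(v - 1) < 1e-12)) stop("relative sensitivity undefined at D = Ca/(1.6 lambda)")
  1 / (2 * v - 2)
}

#' @rdname rel_sens_D
#' @export
rel_sens_I <- function(I, p) {
  if (any(I < 0)) stop("I must be non-negative")
  p$gamma / (p$iota * I + p$gamma)
}

#' Young-minus-old conductance difference over a driver grid
#'
#' Evaluates the conductance under two parameter sets on the outer grid
#' of vapour deficit and light and returns the elementwise difference,
#' the quantity contoured when comparing age groups.
#'
#' @param p_young,p_old stomatal parameters of the two groups.
#' @param D_grid,I_grid strictly positive grid vectors.
#' @param Ca CO2 concentration (mol m^-3).
#' @return matrix (length(D_grid) x length(I_grid)) of g_young - g_old
#'   (m s^-1), with `D_grid`/`I_grid` attached as dimnames.
#' @export
conductance_difference_surface <- function(p_young, p_old, D_grid, I_grid, Ca) {
  stopifnot(all(D_grid > 0), all(I_grid > 0))
  gy <- outer(D_grid, I_grid, function(d, i) conductance(d, i, p_young, Ca))
  go <- outer(D_grid, I_grid, function(d, i) conductance(d, i, p_old, Ca))
  out <- gy - go
  dimnames(out) <- list(D = signif(D_grid, 6), I = signif(I_grid, 6))
  out
}
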
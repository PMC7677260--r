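#' Physical constants used throughout the package
#'
#' @format A named list:
#' \describe{
#'   \item{P0}{Standard atmospheric pressure, 101325 Pa.}
#'   \item{R_gas}{Ideal gas constant, 8.3145 J K^-1 mol^-1.}
#'   \item{water_molar_density}{Molar density of liquid water at 20 degC,
#'     55345 mol m^-3; used to convert volumetric sap flow (m s^-1) to a
#'     molar flux (mol m^-2 s^-1).}
#'   \item{granier_coef, granier_exp}{Coefficient (118.99e-6 m s^-1) and
#'     exponent (1.231) of the Granier thermal-dissipation calibration.}
#' }
#' @export
sapflow_constants <- list(
  P0 = 101325,
  R_gas = 8.3145,
  water_molar_density = 55345,
  granier_coef = 118.99e-6,
  granier_exp = 1.231
)

#' Vapour pressure deficit from air temperature and relative humidity
#'
#' Buck-form saturation vapour pressure with an enhancement factor for
#' moist air at standard pressure:
#' \deqn{VPD = (1 - h_r/100)\,(1.0007 + 3.46\times10^{-8} P_0)\,
#'   611.21\,\exp\!\big[(18.678 - T/234.5)\,T/(257.14 + T)\big]}
#'
#' @param temp_c air temperature (degC).
#' @param rh relative humidity (%), in \[0, 100\].
#' @return VPD in Pa (0 at saturation).
#' @export
vpd_pa <- function(temp_c, rh) {
  if (any(rh < -1e-9 | rh > 100 + 1e-9, na.rm = TRUE)) {
    stop("relative humidity must lie in [0, 100]")
  }
  rh <- pmin(pmax(rh, 0), 100)
  es <- 611.21 * exp((18.678 - temp_c / 234.5) * temp_c / (257.14 + temp_c))
  (1 - rh / 100) * (1.0007 + 3.46e-8 * sapflow_constants$P0) * es
}

#' Convert a vapour pressure deficit (Pa) to a molar concentration
#'
#' Ideal-gas conversion \eqn{D = VPD / (R (T + 273.15))}, the unit the
#' stomatal model works in.
#'
#' @param vpd vapour pressure deficit (Pa).
#' @param temp_c air temperature (degC), must exceed -273.15.
#' @return vapour deficit D (mol m^-3).
#' @export
vpd_molar <- function(vpd, temp_c) {
  if (any(temp_c <= -273.15, na.rm = TRUE)) stop("temperature below absolute zero")
  vpd / (sapflow_constants$R_gas * (temp_c + 273.15))
}

#' Convert a CO2 mixing ratio (ppm) to a molar concentration
#'
#' @param ppm CO2 mixing ratio (ppm).
#' @param temp_c air temperature (degC).
#' @param pressure_pa total pressure (Pa), default standard atmosphere.
#' @return CO2 concentration (mol m^-3).
#' @export
co2_molar <- function(ppm, temp_c, pressure_pa = sapflow_constants$P0) {
  ppm * 1e-6 * pressure_pa / (sapflow_constants$R_gas * (temp_c + 273.15))
}

#' Convert volumetric sap flow density (m s^-1) to a molar flux
#'
#' Multiplies by the molar density of liquid water (55,345 mol m^-3 at
#' 20 degC, configurable), giving mol m^-2 sapwood s^-1.
#'
#' @param j_ms sap flow density (m s^-1), non-negative.
#' @param molar_density molar density of water (mol m^-3).
#' @return molar sap flow density (mol m^-2 s^-1).
#' @export
molar_flux <- function(j_ms, molar_density = sapflow_constants$water_molar_density) {
  if (any(j_ms < 0, na.rm = TRUE)) stop("sap flow density must be non-negative")
  j_ms * molar_density
}
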
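#' Dissolved-oxygen saturation concentration in fresh water
#'
#' Equilibrium (100% air saturation) oxygen concentration as a function of
#' water temperature, barometric pressure and salinity, using the
#' Benson--Krause formulation adopted for the standard USGS/APHA dissolved
#' oxygen tables.
#'
#' The base equation gives the unit standard atmospheric concentration in
#' mg L-1 from the absolute temperature; a salinity factor and a pressure
#' factor (including the water-vapour correction) then rescale it. The
#' formulation is valid for 0--40 degC; we allow up to 45 degC since warm
#' ramp work approaches that bound, at slightly reduced accuracy.
#'
#' @param temp_C water temperature, degrees Celsius (0--45)
#' @param pressure_kPa barometric pressure in kPa (default sea level 101.325)
#' @param salinity_psu salinity, practical salinity units (default 0,
#'   fresh water)
#' @return saturation concentration, umol O2 per litre
#' @examples
#' o2_solubility_umol_l(25)     # ~258 umol L-1 (~8.26 mg L-1)
#' @export
o2_solubility_umol_l <- function(temp_C, pressure_kPa = 101.325,
                                 salinity_psu = 0) {
  if (any(!is.finite(temp_C)) || any(temp_C < 0) || any(temp_C > 45)) {
    stop("temp_C outside the solubility model's validity range [0, 45]")
  }
  if (any(pressure_kPa <= 0)) stop("pressure_kPa must be positive")
  if (any(salinity_psu < 0)) stop("salinity_psu must be non-negative")

  TK <- temp_C + 273.15
  # Benson & Krause base equation, mg/L at 1 atm moist air
  lnC <- -139.34411 + 1.575701e5 / TK - 6.642308e7 / TK^2 +
    1.2438e10 / TK^3 - 8.621949e11 / TK^4
  # salinity factor
  Fs <- exp(-salinity_psu * (0.017674 - 10.754 / TK + 2140.7 / TK^2))
  # pressure factor, P in atm
  P <- pressure_kPa / 101.325
  u <- exp(11.8571 - 3840.70 / TK - 216961 / TK^2)  # vapour pressure, atm
  theta <- 0.000975 - 1.426e-5 * temp_C + 6.436e-8 * temp_C^2
  Fp <- P * (1 - u / P) * (1 - theta * P) / ((1 - u) * (1 - theta))

  mg_l <- exp(lnC) * Fs * Fp
  mg_l / 31.9988 * 1000  # molar mass of O2 -> umol/L
}

#' Convert percent air saturation to oxygen concentration
#'
#' @param sat_pct percent air saturation (0 = anoxic, 100 = equilibrium)
#' @param temp_C water temperature, degrees Celsius
#' @param pressure_kPa barometric pressure, kPa
#' @param salinity_psu salinity, PSU
#' @return dissolved oxygen, umol O2 per litre
#' @export
sat_to_conc <- function(sat_pct, temp_C, pressure_kPa = 101.325,
                        salinity_psu = 0) {
  if (any(sat_pct < 0, na.rm = TRUE)) stop("sat_pct must be non-negative")
  (sat_pct / 100) * o2_solubility_umol_l(temp_C, pressure_kPa, salinity_psu)
}
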
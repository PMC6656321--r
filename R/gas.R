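#' Gas conditions for oxygen unit conversions
#'
#' Bundles the water and atmosphere properties needed to convert between
#' dissolved-oxygen concentration (mg l-1), percent air saturation and
#' partial pressure (mmHg).
#'
#' @param temperature Water temperature in degrees Celsius (0-40).
#' @param salinity Practical salinity (0-40 psu). Default 35, appropriate for
#'   near-oceanic coastal lagoon water.
#' @param barometric_pressure Barometric pressure in mmHg. Default 760.
#' @param o2_mole_fraction Mole fraction of oxygen in dry air. Default 0.2095.
#' @return An object of class `gas_conditions`.
#' @examples
#' gc <- gas_conditions(28)
#' o2_saturation_concentration(gc)
#' @export
gas_conditions <- function(temperature, salinity = 35,
                           barometric_pressure = 760,
                           o2_mole_fraction = 0.2095) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L)
  if (temperature < 0 || temperature > 40)
    stop("temperature must be within 0-40 degrees C")
  if (salinity < 0 || salinity > 40)
    stop("salinity must be within 0-40 psu")
  if (barometric_pressure <= 0) stop("barometric_pressure must be positive")
  structure(
    list(temperature = temperature, salinity = salinity,
         barometric_pressure = barometric_pressure,
         o2_mole_fraction = o2_mole_fraction),
    class = "gas_conditions"
  )
}

#' Saturation water vapour pressure over fresh water
#'
#' @param temperature Degrees Celsius.
#' @return Vapour pressure in mmHg.
#' @export
water_vapour_pressure <- function(temperature) {
  tk <- temperature + 273.15
  760 * exp(11.8571 - 3840.70 / tk - 216961 / tk^2)
}

#' Oxygen concentration at 100% air saturation
#'
#' Benson-Krause solubility fit for dissolved oxygen in equilibrium with
#' water-saturated air, with salinity and barometric-pressure correction
#' factors. Returns mg O2 per litre.
#'
#' @param conditions A [gas_conditions()] object.
#' @return Saturation concentration in mg l-1.
#' @export
o2_saturation_concentration <- function(conditions) {
  stopifnot(inherits(conditions, "gas_conditions"))
  t <- conditions$temperature
  tk <- t + 273.15
  ln_c <- -139.34411 + 1.575701e5 / tk - 6.642308e7 / tk^2 +
    1.243800e10 / tk^3 - 8.621949e11 / tk^4
  f_sal <- exp(-conditions$salinity *
                 (0.017674 - 10.754 / tk + 2140.7 / tk^2))
  p_atm <- conditions$barometric_pressure / 760
  u <- water_vapour_pressure(t) / 760
  theta <- 0.000975 - 1.426e-5 * t + 6.436e-8 * t^2
  f_press <- ((p_atm - u) * (1 - theta * p_atm)) /
    ((1 - u) * (1 - theta))
  exp(ln_c) * f_sal * f_press
}

#' Ambient partial pressure of oxygen
#'
#' Partial pressure of oxygen in water-saturated air at the given barometric
#' pressure: (P - vapour pressure) x mole fraction of O2.
#'
#' @inheritParams o2_saturation_concentration
#' @return pO2 in mmHg.
#' @export
ambient_po2 <- function(conditions) {
  stopifnot(inherits(conditions, "gas_conditions"))
  (conditions$barometric_pressure -
     water_vapour_pressure(conditions$temperature)) *
    conditions$o2_mole_fraction
}

#' Convert critical saturation to critical partial pressure
#'
#' @param scrit Critical oxygen saturation as a fraction in [0, 1].
#' @inheritParams o2_saturation_concentration
#' @return P_crit in mmHg.
#' @examples
#' pcrit_from_scrit(0.51, gas_conditions(28))
#' @export
pcrit_from_scrit <- function(scrit, conditions) {
  if (!is.numeric(scrit) || any(scrit < 0) || any(scrit > 1))
    stop("scrit must lie in [0, 1]")
  scrit * ambient_po2(conditions)
}

#' Convert between concentration and percent saturation
#'
#' @param o2_conc Dissolved oxygen in mg l-1.
#' @inheritParams o2_saturation_concentration
#' @return Percent air saturation.
#' @export
o2_conc_to_sat <- function(o2_conc, conditions) {
  100 * o2_conc / o2_saturation_concentration(conditions)
}

#' @rdname o2_conc_to_sat
#' @param o2_sat Percent air saturation.
#' @export
o2_sat_to_conc <- function(o2_sat, conditions) {
  o2_sat / 100 * o2_saturation_concentration(conditions)
}
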
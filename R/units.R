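#' Gas-phase reference conditions
#'
#' Temperature and pressure used for ideal-gas conversions between mass and
#' mixing-ratio units. Defaults are 20 degrees C and 1 atm, which reproduce
#' the standard benchmark pairs for NO2 (10 ug/m3 = 5.2 ppbv; a burner emitting
#' 25 mL/h emits 48 mg/h). The molar mass of NO2 is fixed at 46.0055 g/mol.
#'
#' @param temperature_c Air temperature, degrees Celsius.
#' @param pressure_pa Air pressure, Pa.
#' @return An object of class `gas_conditions`: a list with `temperature_k`,
#'   `pressure_pa` and `molar_mass` (g/mol).
#' @examples
#' cond <- gas_conditions()
#' ugm3_to_ppbv(10, cond) # ~5.2 ppbv
#' @export
gas_conditions <- function(temperature_c = 20, pressure_pa = 101325) {
  temperature_k <- temperature_c + 273.15
  if (!is.finite(temperature_k) || temperature_k <= 0)
    stop("temperature must be above absolute zero", call. = FALSE)
  if (!is.finite(pressure_pa) || pressure_pa <= 0)
    stop("pressure must be positive", call. = FALSE)
  structure(
    list(temperature_k = temperature_k, pressure_pa = pressure_pa,
         molar_mass = 46.0055),
    class = "gas_conditions"
  )
}

# ideal-gas molar volume, L/mol
molar_volume_l <- function(cond) {
  8.314462618 * cond$temperature_k / cond$pressure_pa * 1000
}

#' Convert NO2 mass concentration to mixing ratio
#'
#' Ideal-gas conversion from ug/m3 to parts per billion by volume.
#'
#' @param conc Concentration, ug/m3 (non-negative).
#' @param cond A [gas_conditions()] object.
#' @return Concentration in ppbv.
#' @export
ugm3_to_ppbv <- function(conc, cond = gas_conditions()) {
  stopifnot(inherits(cond, "gas_conditions"))
  if (any(conc < 0)) stop("concentration must be non-negative", call. = FALSE)
  conc * molar_volume_l(cond) / cond$molar_mass
}

#' Convert NO2 mixing ratio to mass concentration
#'
#' Inverse of [ugm3_to_ppbv()].
#'
#' @param ppbv Concentration, ppbv (non-negative).
#' @inheritParams ugm3_to_ppbv
#' @return Concentration in ug/m3.
#' @export
ppbv_to_ugm3 <- function(ppbv, cond = gas_conditions()) {
  stopifnot(inherits(cond, "gas_conditions"))
  if (any(ppbv < 0)) stop("concentration must be non-negative", call. = FALSE)
  ppbv * cond$molar_mass / molar_volume_l(cond)
}

#' Convert a volumetric NO2 emission rate to a mass rate
#'
#' Converts mL/h of NO2 (as an ideal gas at the given conditions) to mg/h.
#' At 20 degrees C and 1 atm, 25 mL/h corresponds to 48 mg/h.
#'
#' @param vol_rate Emission rate, mL/h (non-negative).
#' @inheritParams ugm3_to_ppbv
#' @return Emission rate in mg/h.
#' @export
mlh_to_mgh <- function(vol_rate, cond = gas_conditions()) {
  stopifnot(inherits(cond, "gas_conditions"))
  if (any(vol_rate < 0)) stop("emission rate must be non-negative", call. = FALSE)
  vol_rate * cond$molar_mass / molar_volume_l(cond)
}

# mg/m3 -> ppbv (used internally for stove-species output)
mgm3_to_ppbv <- function(conc, cond = gas_conditions()) {
  ugm3_to_ppbv(conc * 1000, cond)
}
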
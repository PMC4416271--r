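# Moist-air property correlations used throughout the model.
#
# Saturation vapour pressure follows the Arden Buck (1981) fit over liquid
# water; vapour density then comes from the ideal-gas law with the water
# vapour gas constant. Dry-air transport properties use standard textbook
# correlations (Sutherland viscosity, power-law conductivity/diffusivity).

R_VAPOUR <- 461.5    # J/(kg K), specific gas constant of water vapour
R_DRY_AIR <- 287.05  # J/(kg K), specific gas constant of dry air
KELVIN0 <- 273.15
TEMP_VALID_C <- c(-20, 50)  # validity window of the correlations, degC
P_STANDARD <- 101325        # Pa

#' Check a temperature against the correlation validity range
#'
#' @param t_c temperature(s), degC
#' @param what label used in the error message
#' @return invisibly, `t_c`
#' @keywords internal
check_temperature_range <- function(t_c, what = "temperature") {
  if (length(t_c) == 0L || any(!is.finite(t_c))) {
    stop(sprintf("%s must be finite", what), call. = FALSE)
  }
  if (any(t_c < TEMP_VALID_C[1]) || any(t_c > TEMP_VALID_C[2])) {
    stop(sprintf(
      "%s out of the correlation validity range [%g, %g] degC",
      what, TEMP_VALID_C[1], TEMP_VALID_C[2]
    ), call. = FALSE)
  }
  invisible(t_c)
}

#' Saturation vapour pressure of water (Arden Buck form)
#'
#' @param t_c air temperature, degC
#' @return saturation vapour pressure over liquid water, Pa
#' @keywords internal
saturation_vapour_pressure <- function(t_c) {
  check_temperature_range(t_c)
  611.21 * exp((18.678 - t_c / 234.5) * t_c / (257.14 + t_c))
}

#' Saturation water-vapour density
#'
#' Mass concentration of water vapour in saturated air, from the Arden Buck
#' saturation pressure converted with the ideal-gas law (gas constant of
#' water vapour 461.5 J/(kg K)). Strictly increasing in temperature.
#'
#' @param t_c air temperature, degC; valid on \[-20, 50\]
#' @return saturation vapour density, kg/m^3
#' @examples
#' saturation_vapour_density(23) # about 0.0206 kg/m^3
#' @export
saturation_vapour_density <- function(t_c) {
  saturation_vapour_pressure(t_c) / (R_VAPOUR * (t_c + KELVIN0))
}

#' Absolute humidity of moist air
#'
#' @param t_c air temperature, degC
#' @param rh relative humidity, fraction in \[0, 1\]
#' @return water-vapour mass concentration, kg/m^3
#' @examples
#' absolute_humidity(23, 0.45) * 1000 # about 9.2 g/m^3
#' @export
absolute_humidity <- function(t_c, rh) {
  if (any(!is.finite(rh)) || any(rh < 0) || any(rh > 1)) {
    stop("relative humidity must lie in [0, 1]", call. = FALSE)
  }
  rh * saturation_vapour_density(t_c)
}

#' Dry-air transport properties
#'
#' Ideal-gas density, Sutherland dynamic viscosity, power-law thermal
#' conductivity and water-vapour-in-air diffusivity, and a constant specific
#' heat. All values are continuous in temperature over the validity range.
#'
#' @param t_c air temperature, degC
#' @param pressure barometric pressure, Pa (default standard atmosphere)
#' @return list with `density` (kg/m^3), `dynamic_viscosity` (Pa s),
#'   `thermal_conductivity` (W/(m K)), `specific_heat` (J/(kg K)) and
#'   `vapour_diffusivity` (m^2/s)
#' @export
air_transport_properties <- function(t_c, pressure = P_STANDARD) {
  check_temperature_range(t_c)
  stopifnot(is.numeric(pressure), pressure > 0)
  t_k <- t_c + KELVIN0
  list(
    density = pressure / (R_DRY_AIR * t_k),
    # Sutherland (S = 110.4 K, mu_ref = 1.716e-5 Pa s at 273.15 K)
    dynamic_viscosity = 1.716e-5 * (t_k / KELVIN0)^1.5 *
      (KELVIN0 + 110.4) / (t_k + 110.4),
    thermal_conductivity = 0.02624 * (t_k / 300)^0.8646,
    specific_heat = 1006,
    # binary diffusivity of water vapour in air, pressure-scaled
    vapour_diffusivity = 2.178e-5 * (t_k / KELVIN0)^1.81 * (P_STANDARD / pressure)
  )
}

#' Ambient air condition
#'
#' Container for the inhaled-air boundary condition: temperature, relative
#' humidity and barometric pressure. Absolute humidity is derived on demand
#' via [absolute_humidity()], not stored.
#'
#' @param temperature air temperature, degC
#' @param relative_humidity fraction in \[0, 1\]
#' @param pressure barometric pressure, Pa
#' @return object of class `ambient_air`
#' @examples
#' amb <- ambient_air(23, 0.45)
#' ambient_vapour_density(amb) # inlet vapour concentration, kg/m^3
#' @export
ambient_air <- function(temperature = 23, relative_humidity = 0.45,
                        pressure = P_STANDARD) {
  check_temperature_range(temperature, "ambient temperature")
  if (!is.numeric(relative_humidity) || length(relative_humidity) != 1L ||
      !is.finite(relative_humidity) ||
      relative_humidity < 0 || relative_humidity > 1) {
    stop("relative_humidity must be a single value in [0, 1]", call. = FALSE)
  }
  stopifnot(is.numeric(pressure), length(pressure) == 1L, pressure > 0)
  structure(
    list(
      temperature = temperature,
      relative_humidity = relative_humidity,
      pressure = pressure
    ),
    class = "ambient_air"
  )
}

#' Inlet water-vapour concentration of an ambient condition
#'
#' @param ambient an [ambient_air()] object
#' @return vapour mass concentration, kg/m^3
#' @export
ambient_vapour_density <- function(ambient) {
  stopifnot(inherits(ambient, "ambient_air"))
  absolute_humidity(ambient$temperature, ambient$relative_humidity)
}

#' @export
print.ambient_air <- function(x, ...) {
  cat(sprintf(
    "Ambient air: %.1f degC, RH %.0f%%, %.0f Pa (AH %.2f g/m^3)\n",
    x$temperature, 100 * x$relative_humidity, x$pressure,
    1000 * ambient_vapour_density(x)
  ))
  invisible(x)
}
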
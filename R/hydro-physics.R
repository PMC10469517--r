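# Evaporative and physical-property primitives shared by the analytical
# threshold, the simulator and the synthetic generators.

#' Molar mass of water (g/mol)
#' @keywords internal
.M_WATER <- 18.015

#' Standard atmospheric pressure (kPa)
#' @keywords internal
.P_ATM <- 101.325

#' Ambient air state
#'
#' Bundles the three quantities every vapour-flux computation needs:
#' air temperature, relative humidity and atmospheric pressure. Organ
#' temperature is assumed equal to air temperature throughout the package.
#'
#' @param temperature Air temperature, degrees Celsius. Must lie in
#'   \[-20, 60\].
#' @param relative_humidity Relative humidity, percent (0-100).
#' @param pressure Atmospheric pressure, kPa. Default 101.325.
#' @return An object of class `air_state` with fields `temperature`,
#'   `relative_humidity` and `pressure`.
#' @examples
#' air_state(40, 12)
#' @export
air_state <- function(temperature, relative_humidity, pressure = .P_ATM) {
  stopifnot(is.numeric(temperature), is.numeric(relative_humidity),
            is.numeric(pressure), length(pressure) %in% c(1L, length(temperature)))
  if (any(!is.finite(temperature)) || any(temperature < -20 | temperature > 60))
    stop("temperature must be finite and within [-20, 60] degC")
  if (any(!is.finite(relative_humidity)) ||
      any(relative_humidity < 0 | relative_humidity > 100))
    stop("relative_humidity must be within [0, 100] %")
  if (any(!is.finite(pressure)) || any(pressure <= 0))
    stop("pressure must be positive")
  structure(list(temperature = temperature,
                 relative_humidity = relative_humidity,
                 pressure = pressure),
            class = "air_state")
}

#' @export
print.air_state <- function(x, ...) {
  cat(sprintf("<air_state> T = %g degC, RH = %g %%, P = %g kPa (VPD = %.3f kPa)\n",
              x$temperature[1], x$relative_humidity[1], x$pressure[1],
              vapor_pressure_deficit(x)[1]))
  invisible(x)
}

#' Saturation vapour pressure (Buck equation)
#'
#' e_sat(T) = 0.61121 * exp(17.502 T / (240.97 + T)) kPa, with T in degrees
#' Celsius.
#'
#' @param temperature Air temperature, degC.
#' @return Saturation vapour pressure, kPa.
#' @export
saturation_vapor_pressure <- function(temperature) {
  0.61121 * exp(17.502 * temperature / (240.97 + temperature))
}

#' Vapour pressure deficit
#'
#' VPD = (1 - RH/100) * e_sat(T), the evaporative driving force used by every
#' flux conversion in the package.
#'
#' @param air An [air_state()].
#' @return VPD in kPa (vectorised over the air state's fields).
#' @examples
#' vapor_pressure_deficit(air_state(40, 12)) # ~6.5 kPa
#' @export
vapor_pressure_deficit <- function(air) {
  stopifnot(inherits(air, "air_state"))
  (1 - air$relative_humidity / 100) * saturation_vapor_pressure(air$temperature)
}

#' Convert between residual transpiration and residual conductance
#'
#' E = g * VPD / P_atm and g = E * P_atm / VPD. Both quantities are per
#' projected organ area, mmol m-2 s-1 (conductance has the same molar units
#' because VPD/P_atm is dimensionless).
#'
#' @param value Flux (`direction = "g2E"`: a conductance g_res;
#'   `"E2g"`: a transpiration rate E_res), mmol m-2 s-1.
#' @param air An [air_state()].
#' @param direction `"g2E"` (conductance to transpiration, the forward Eq.)
#'   or `"E2g"` (its inverse).
#' @return Converted value, mmol m-2 s-1.
#' @examples
#' convert_flux(13.98, air_state(40, 12), "g2E") # ~0.90
#' @export
convert_flux <- function(value, air, direction = c("g2E", "E2g")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(value), all(value >= 0))
  vpd <- vapor_pressure_deficit(air)
  if (direction == "g2E") {
    value * vpd / air$pressure
  } else {
    if (any(vpd <= 0))
      stop("cannot convert E to g at zero VPD (saturated air): singular")
    value * air$pressure / vpd
  }
}

#' Batch flux conversion table
#'
#' Converts a table of residual conductances/transpirations row by row.
#'
#' @param df data.frame with columns `temp_C`, `rh_pct`, `value`,
#'   `direction` (`"g2E"` or `"E2g"`).
#' @return The input with a `converted` column appended.
#' @export
convert_flux_table <- function(df) {
  need <- c("temp_C", "rh_pct", "value", "direction")
  if (!all(need %in% names(df)))
    stop("need columns: ", paste(need, collapse = ", "))
  df$converted <- vapply(seq_len(nrow(df)), function(i)
    convert_flux(df$value[i], air_state(df$temp_C[i], df$rh_pct[i]),
                 df$direction[i]),
    numeric(1))
  df
}

#' Dynamic viscosity of water relative to 20 degC (Korson-type fit)
#'
#' log10(mu(T)/mu(20)) = (1.1709 (20 - T) - 0.001827 (T - 20)^2) / (T + 89.93).
#'
#' @param temperature Water temperature, degC (0-60).
#' @return mu(T)/mu(20 degC), dimensionless.
#' @keywords internal
.viscosity_rel20 <- function(temperature) {
  10^((1.1709 * (20 - temperature) - 0.001827 * (temperature - 20)^2) /
        (temperature + 89.93))
}

#' Temperature ratio of water viscosity
#'
#' Returns mu(T_ref)/mu(T): the factor by which hydraulic conductance
#' increases when the sap warms from `t_ref` to `t` (conductance scales with
#' fluidity, the reciprocal of viscosity).
#'
#' @param t_ref Reference temperature, degC (0-60).
#' @param t Target temperature, degC (0-60).
#' @return Dimensionless ratio; 1 when `t == t_ref`.
#' @examples
#' water_viscosity_ratio(20, 40) # ~1.534
#' @export
water_viscosity_ratio <- function(t_ref, t) {
  if (any(c(t_ref, t) < 0 | c(t_ref, t) > 60))
    stop("temperatures must be within [0, 60] degC")
  .viscosity_rel20(t_ref) / .viscosity_rel20(t)
}

#' Viscosity correction of hydraulic conductance
#'
#' K(T) = K(T_ref) * mu(T_ref)/mu(T). Warmer, less viscous sap flows more
#' easily through the same xylem.
#'
#' @param k_ref Hydraulic conductance at `t_ref`, mmol m-2 s-1 MPa-1.
#' @param t_ref Reference temperature, degC.
#' @param t Target temperature, degC.
#' @return Corrected conductance at `t`.
#' @examples
#' correct_conductance(2.60, 20, 40) # ~3.99
#' @export
correct_conductance <- function(k_ref, t_ref, t) {
  if (any(k_ref < 0)) stop("conductance must be non-negative")
  k_ref * water_viscosity_ratio(t_ref, t)
}

#' Gravimetric mass loss to molar water flux
#'
#' Converts a weighing-series mass difference into a transpiration flux:
#' flux = (dm / 18.015 g mol-1 * 1000) / (dt * area), mmol m-2 s-1.
#'
#' @param dm Mass lost, g (>= 0).
#' @param dt Elapsed time, s (> 0).
#' @param area Projected organ area, m2 (> 0).
#' @return Flux in mmol m-2 s-1.
#' @export
mass_loss_to_flux <- function(dm, dt, area) {
  if (any(dm < 0)) stop("dm must be non-negative")
  if (any(dt <= 0) || any(area <= 0)) stop("dt and area must be positive")
  (dm / .M_WATER * 1000) / (dt * area)
}

#' Surface tension of water (IAPWS-style fit)
#'
#' sigma(T) = 235.8 (1 - T_K/647.096)^1.256 (1 - 0.625 (1 - T_K/647.096))
#' mN/m. Used to rescale cavitation thresholds with temperature: the air-seed
#' tension a pit membrane can sustain is proportional to surface tension.
#'
#' @param temperature Temperature, degC.
#' @return Surface tension, mN/m.
#' @export
water_surface_tension <- function(temperature) {
  tau <- 1 - (temperature + 273.15) / 647.096
  235.8 * tau^1.256 * (1 - 0.625 * tau)
}

#' Temperature ratio of water surface tension
#'
#' sigma(T)/sigma(T_ref); multiplies P50 in the simulator's temperature
#' response (P50 becomes less negative as surface tension falls with warming).
#'
#' @param t_ref Reference temperature, degC (0-60).
#' @param t Target temperature, degC (0-60).
#' @return Dimensionless ratio; < 1 for `t > t_ref`.
#' @examples
#' surface_tension_ratio(20, 40) # ~0.956
#' @export
surface_tension_ratio <- function(t_ref, t) {
  if (any(c(t_ref, t) < 0 | c(t_ref, t) > 60))
    stop("temperatures must be within [0, 60] degC")
  water_surface_tension(t) / water_surface_tension(t_ref)
}
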
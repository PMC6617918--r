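#' Barometric pressure model
#'
#' International Standard Atmosphere (ISA) troposphere model:
#' \deqn{P(z) = P_0 (1 - L z / T_0)^{g M / (R L)}}
#' with sea-level pressure \eqn{P_0 = 101.325} kPa, lapse rate
#' \eqn{L = 0.0065} K/m, sea-level temperature \eqn{T_0 = 288.15} K and
#' exponent \eqn{g M / (R L) \approx 5.25588}. Altitude is the sole driver
#' of pressure; weather variation is ignored. All constants are
#' configurable so an alternative barometric parameterisation can be
#' matched exactly.
#'
#' @param sea_level_pressure Sea-level pressure, kPa.
#' @param lapse_rate Temperature lapse rate, K/m.
#' @param sea_level_temperature Sea-level temperature, K.
#' @param exponent Dimensionless barometric exponent g*M/(R*L).
#' @return An object of class `atmosphere_model`.
#' @examples
#' atm <- atmosphere_model()
#' pressure_at_altitude(atm, c(0, 1842, 3490))
#' @export
atmosphere_model <- function(sea_level_pressure = 101.325,
                             lapse_rate = 0.0065,
                             sea_level_temperature = 288.15,
                             exponent = 5.25588) {
  check_number(sea_level_pressure, "sea_level_pressure")
  check_number(lapse_rate, "lapse_rate")
  check_number(sea_level_temperature, "sea_level_temperature")
  check_number(exponent, "exponent")
  stopifnot(sea_level_pressure > 0, lapse_rate > 0,
            sea_level_temperature > 0, exponent > 0)
  structure(list(sea_level_pressure = sea_level_pressure,
                 lapse_rate = lapse_rate,
                 sea_level_temperature = sea_level_temperature,
                 exponent = exponent),
            class = "atmosphere_model")
}

#' @export
print.atmosphere_model <- function(x, ...) {
  cat("<atmosphere_model> ISA troposphere: P0 =",
      format(x$sea_level_pressure), "kPa, L =", format(x$lapse_rate),
      "K/m, T0 =", format(x$sea_level_temperature), "K, exponent =",
      format(x$exponent), "\n")
  invisible(x)
}

# troposphere validity range, metres
ALTITUDE_RANGE <- c(-500, 11000)

#' Ambient pressure at an altitude
#'
#' @param atm An [atmosphere_model()].
#' @param z Altitude(s) in metres, within \[-500, 11000\] (troposphere).
#' @return Pressure(s) in kPa.
#' @export
pressure_at_altitude <- function(atm, z) {
  stopifnot(inherits(atm, "atmosphere_model"))
  check_number(z, "z", lower = ALTITUDE_RANGE[1], upper = ALTITUDE_RANGE[2],
               allow_vector = TRUE)
  atm$sea_level_pressure *
    (1 - atm$lapse_rate * z / atm$sea_level_temperature)^atm$exponent
}

#' Altitude at an ambient pressure
#'
#' Closed-form inverse of [pressure_at_altitude()].
#'
#' @param atm An [atmosphere_model()].
#' @param p Pressure(s) in kPa, within the troposphere pressure range.
#' @return Altitude(s) in metres.
#' @export
altitude_at_pressure <- function(atm, p) {
  stopifnot(inherits(atm, "atmosphere_model"))
  p_range <- pressure_at_altitude(atm, rev(ALTITUDE_RANGE))
  check_number(p, "p", lower = p_range[1], upper = p_range[2],
               allow_vector = TRUE)
  atm$sea_level_temperature / atm$lapse_rate *
    (1 - (p / atm$sea_level_pressure)^(1 / atm$exponent))
}

# exact conversion factor: 1 kPa = 7.500617 mmHg
KPA_PER_MMHG <- 1 / 7.500617

#' Convert between kPa and mmHg
#'
#' Clinical sources often quote pressures in mmHg (e.g. aircraft cabin
#' pressurisation limits); the internal unit is kPa. Conversion uses
#' 1 kPa = 7.500617 mmHg.
#'
#' @param p Pressure(s) in the source unit.
#' @return Pressure(s) in the target unit.
#' @export
kpa_to_mmhg <- function(p) p * 7.500617

#' @rdname kpa_to_mmhg
#' @export
mmhg_to_kpa <- function(p) p * KPA_PER_MMHG

#' Read model constants from a YAML or JSON config file
#'
#' Recognised keys: `sea_level_pressure_kpa`, `lapse_rate_k_per_m`,
#' `sea_level_temperature_k`, `exponent` (atmosphere);
#' `total_volume_ml` (geometry); `anterior_chamber_ml`, `thresholds`
#' (risk policy). Missing keys fall back to the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `atm`, `geom`, `policy`.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "gasrisk_io_error")
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  atm <- atmosphere_model(
    sea_level_pressure = cfg$sea_level_pressure_kpa %||% 101.325,
    lapse_rate = cfg$lapse_rate_k_per_m %||% 0.0065,
    sea_level_temperature = cfg$sea_level_temperature_k %||% 288.15,
    exponent = cfg$exponent %||% 5.25588)
  geom <- vitreous_geometry(total_volume = cfg$total_volume_ml %||% 4.5)
  policy <- risk_policy(
    anterior_chamber_volume = cfg$anterior_chamber_ml %||% 0.20,
    thresholds = unlist(cfg$thresholds) %||% c(0.5, 1.0))
  list(atm = atm, geom = geom, policy = policy)
}
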
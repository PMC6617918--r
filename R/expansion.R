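#' Risk policy for intraocular-pressure elevation
#'
#' The calculator's risk estimate is the ratio of the unconstrained gas
#' volume increase to the normal anterior-chamber volume. The categorical
#' report maps the ratio onto ordered labels `none < low < moderate < high`
#' using two ascending cut points with a closed-left convention (a ratio
#' exactly at a threshold lands in the higher category). Any non-positive
#' volume change (flat route or descent) is labelled `none`.
#'
#' The published calculator does not print its cut-offs or the
#' anterior-chamber constant; the defaults here (0.20 ml chamber, cuts at
#' 0.5 and 1.0) are anatomically conventional placeholders, fully
#' configurable.
#'
#' @param anterior_chamber_volume Normal anterior-chamber volume, ml.
#' @param thresholds Two strictly ascending cut points on the risk ratio
#'   delimiting low/moderate/high.
#' @return An object of class `risk_policy`.
#' @export
risk_policy <- function(anterior_chamber_volume = 0.20,
                        thresholds = c(0.5, 1.0)) {
  check_number(anterior_chamber_volume, "anterior_chamber_volume")
  check_number(thresholds, "thresholds", allow_vector = TRUE)
  if (anterior_chamber_volume <= 0) {
    abort("`anterior_chamber_volume` must be > 0.",
          class = "gasrisk_domain_error")
  }
  if (length(thresholds) != 2L || diff(thresholds) <= 0) {
    abort("`thresholds` must be two strictly ascending cut points.",
          class = "gasrisk_domain_error")
  }
  structure(list(anterior_chamber_volume = anterior_chamber_volume,
                 thresholds = thresholds),
            class = "risk_policy")
}

RISK_LEVELS <- c("none", "low", "moderate", "high")

risk_category <- function(risk_ratio, policy) {
  cuts <- policy$thresholds
  dplyr::case_when(
    risk_ratio <= 0 ~ "none",
    risk_ratio >= cuts[2] ~ "high",
    risk_ratio >= cuts[1] ~ "moderate",
    TRUE ~ "low") |>
    factor(levels = RISK_LEVELS, ordered = TRUE)
}

#' Boyle's-law expansion of an intravitreous gas volume
#'
#' Applies \eqn{P_1 V_1 = P_2 V_2} between the ambient pressures at the
#' origin and destination altitudes. The destination volume is the
#' unconstrained Boyle volume: ocular compensation mechanisms (choroidal
#' compression, scleral expansion, aqueous outflow) are deliberately not
#' modelled. `delta_v` is signed -- negative for descent.
#'
#' @param v1 Initial gas volume(s), ml (>= 0).
#' @param z1,z2 Origin and destination altitudes, metres.
#' @param atm An [atmosphere_model()].
#' @return A tibble with columns `v1`, `p1`, `p2`, `v2`, `delta_v`.
#' @examples
#' expand_gas(1.0, 0, 3490)
#' @export
expand_gas <- function(v1, z1, z2, atm = atmosphere_model()) {
  check_number(v1, "v1", lower = 0, allow_vector = TRUE)
  p1 <- pressure_at_altitude(atm, z1)
  p2 <- pressure_at_altitude(atm, z2)
  # group as v1 * (p1/p2) so equal pressures give exactly v2 == v1
  v2 <- v1 * (p1 / p2)
  tibble(v1 = v1, p1 = p1, p2 = p2, v2 = v2, delta_v = v2 - v1)
}

#' Full risk assessment from an interface height and a route
#'
#' Chains the geometry and atmosphere models: interface height (percent)
#' -> initial gas volume -> Boyle expansion over the route -> risk ratio
#' \eqn{r = \Delta V / V_{AC}} against the anterior-chamber volume ->
#' ordered risk category. All arguments are vectorised and recycle to a
#' common length.
#'
#' @param h_pct Interface height(s) as a percentage of the cavity's
#'   vertical extent occupied by gas, in \[0, 100\].
#' @param z1,z2 Origin and destination altitudes, metres.
#' @param geom A [vitreous_geometry()].
#' @param atm An [atmosphere_model()].
#' @param policy A [risk_policy()].
#' @return A tibble with columns `h_pct`, `z1`, `z2`, `v1`, `p1`, `p2`,
#'   `v2`, `delta_v`, `risk_ratio`, `category`.
#' @examples
#' assess_risk(75, 10, 3490)
#' @export
assess_risk <- function(h_pct, z1, z2,
                        geom = vitreous_geometry(),
                        atm = atmosphere_model(),
                        policy = risk_policy()) {
  check_number(h_pct, "h_pct", lower = 0, upper = 100, allow_vector = TRUE)
  n <- max(length(h_pct), length(z1), length(z2))
  h_pct <- rep_len(h_pct, n)
  z1 <- rep_len(z1, n)
  z2 <- rep_len(z2, n)
  v1 <- gas_volume_from_interface(geom, h_pct / 100)
  out <- expand_gas(v1, z1, z2, atm)
  out |>
    dplyr::mutate(h_pct = h_pct, z1 = z1, z2 = z2, .before = 1) |>
    dplyr::mutate(
      risk_ratio = .data$delta_v / policy$anterior_chamber_volume,
      category = risk_category(.data$risk_ratio, policy))
}

#' Structured JSON risk report for a single case
#'
#' @param h_pct Interface height, percent.
#' @param z1,z2 Origin and destination altitudes, metres.
#' @param geom,atm,policy Model components; see [assess_risk()].
#' @param path Optional output path; when given the JSON is written there.
#' @return The report as a nested list (invisibly when `path` is given).
#' @export
risk_report <- function(h_pct, z1, z2,
                        geom = vitreous_geometry(),
                        atm = atmosphere_model(),
                        policy = risk_policy(),
                        path = NULL) {
  res <- assess_risk(h_pct, z1, z2, geom, atm, policy)
  stopifnot(nrow(res) == 1L)
  report <- list(
    inputs = list(interface_pct = res$h_pct,
                  origin_altitude_m = res$z1,
                  destination_altitude_m = res$z2),
    pressures_kpa = list(origin = res$p1, destination = res$p2),
    volumes_ml = list(initial_gas = res$v1, expanded_gas = res$v2,
                      delta = res$delta_v),
    risk = list(ratio = res$risk_ratio,
                category = as.character(res$category)),
    model = list(total_volume_ml = geom$total_volume,
                 anterior_chamber_ml = policy$anterior_chamber_volume,
                 thresholds = policy$thresholds))
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}
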
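#' Vitreous cavity geometry
#'
#' The vitreous cavity is idealised as an oblate spheroid of fixed total
#' volume (default 4.5 ml). A buoyant gas or air bubble occupies the superior
#' part of the cavity, so the fluid/gas interface height -- the fraction of
#' the cavity's vertical diameter occupied by gas, measured downward from the
#' superior pole -- determines the gas volume through the spheroid-cap
#' formula.
#'
#' Because an axis-aligned scaling of a sphere preserves slab-volume
#' fractions as a function of normalised height, the spherical-cap fraction
#' \eqn{f(h) = h^2 (3 - 2h)} is exact for any oblate spheroid with a vertical
#' axis, regardless of aspect ratio. Only the total volume enters the
#' volume mapping; no shape parameter is needed.
#'
#' @param total_volume Cavity volume in ml. Default 4.5 ml, the conventional
#'   adult value; may be inaccurate in e.g. highly myopic eyes.
#' @return An object of class `vitreous_geometry`.
#' @examples
#' geom <- vitreous_geometry()
#' gas_volume_from_interface(geom, 0.5)
#' @export
vitreous_geometry <- function(total_volume = 4.5) {
  check_number(total_volume, "total_volume")
  if (total_volume <= 0) {
    abort("`total_volume` must be > 0.", class = "gasrisk_domain_error")
  }
  structure(list(total_volume = total_volume), class = "vitreous_geometry")
}

#' @export
print.vitreous_geometry <- function(x, ...) {
  cat("<vitreous_geometry> oblate spheroid, total volume",
      format(x$total_volume), "ml\n")
  invisible(x)
}

#' Spheroid-cap volume fraction of the gas bubble
#'
#' Fraction of the cavity volume occupied by a superior cap whose vertical
#' extent is a fraction `h` of the cavity's vertical diameter:
#' \eqn{f(h) = h^2 (3 - 2h)}. Strictly increasing on \[0, 1\] with
#' \eqn{f(h) + f(1-h) = 1}.
#'
#' @param h Fill-height fraction(s) in \[0, 1\].
#' @return Volume fraction(s) in \[0, 1\].
#' @examples
#' cap_volume_fraction(c(0, 0.5, 0.75, 1))
#' @export
cap_volume_fraction <- function(h) {
  check_number(h, "h", lower = 0, upper = 1, allow_vector = TRUE)
  h * h * (3 - 2 * h)
}

#' Gas volume from the fluid/gas interface height
#'
#' @param geom A [vitreous_geometry()].
#' @param h Fill-height fraction(s) in \[0, 1\] (gas measured from the
#'   superior pole downward).
#' @return Gas volume(s) in ml.
#' @examples
#' gas_volume_from_interface(vitreous_geometry(), 0.75)
#' @export
gas_volume_from_interface <- function(geom, h) {
  stopifnot(inherits(geom, "vitreous_geometry"))
  geom$total_volume * cap_volume_fraction(h)
}

#' Interface height from a gas volume
#'
#' Inverse of [gas_volume_from_interface()], solved by bracketed
#' root-finding on \[0, 1\] (tolerance 1e-12 in `h`); the inverse is unique
#' because the cap fraction is strictly increasing.
#'
#' @param geom A [vitreous_geometry()].
#' @param v Gas volume(s) in ml, in \[0, total_volume\].
#' @return Fill-height fraction(s) in \[0, 1\].
#' @examples
#' interface_from_gas_volume(vitreous_geometry(), 2.25)
#' @export
interface_from_gas_volume <- function(geom, v) {
  stopifnot(inherits(geom, "vitreous_geometry"))
  check_number(v, "v", lower = 0, upper = geom$total_volume,
               allow_vector = TRUE)
  vapply(v, function(vi) {
    frac <- vi / geom$total_volume
    if (frac <= 0) return(0)
    if (frac >= 1) return(1)
    uniroot(function(h) h * h * (3 - 2 * h) - frac,
            interval = c(0, 1), tol = 1e-12)$root
  }, numeric(1))
}
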
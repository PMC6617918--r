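# Independent oracles used across the suite.

# cap fraction by numerical slab integration of a unit sphere:
# integrate slice areas pi*(1 - z^2) from z = 1 - 2h up to the top pole
# and divide by the sphere volume 4*pi/3.
cap_fraction_numeric <- function(h) {
  vapply(h, function(hi) {
    stats::integrate(function(z) pi * (1 - z^2), 1 - 2 * hi, 1,
                     rel.tol = 1e-10)$value / (4 * pi / 3)
  }, numeric(1))
}

# ISA troposphere evaluated from first-principles constants, written
# independently of the package implementation
isa_pressure_kpa <- function(z) {
  101.325 * (1 - 0.0065 * z / 288.15)^5.25588
}

# published ISA tabulation (kPa at geometric altitudes), used as the
# external reference for the atmosphere model
isa_table <- data.frame(
  altitude_m = c(0, 1000, 2000, 3000, 4000, 5000),
  pressure_kpa = c(101.325, 89.876, 79.501, 70.121, 61.660, 54.048))
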
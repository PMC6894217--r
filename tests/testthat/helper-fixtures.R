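# Reference five-state spreading table, built in code (identical to the
# packaged extdata/table1.csv).
table1_states <- function() {
  spreading_states(
    state_id = letters[1:5],
    bottom_area_um2 = c(125.09, 243.84, 421.28, 549.88, 696.53),
    height_um = c(15.45, 12.75, 10.96, 9.41, 8.03),
    volume_um3 = c(2988.40, 2998.36, 3000.60, 3000.49, 3010.90)
  )
}

# States lying exactly on an ellipse locus (no noise).
exact_ellipse_states <- function(a, b, r0, volume = 3000) {
  spreading_states(
    state_id = sprintf("p%d", seq_along(r0)),
    bottom_area_um2 = pi * r0^2,
    height_um = b * sqrt(1 - r0^2 / a^2),
    volume_um3 = rep(volume, length(r0))
  )
}

# Closed-form surface area of an oblate spheroid (equatorial a > polar c),
# independent oracle for the quadrature-based zone area.
oblate_spheroid_area <- function(a, c) {
  if (a == c) return(4 * pi * a^2)
  e <- sqrt(1 - c^2 / a^2)
  2 * pi * a^2 * (1 + (1 - e^2) / e * atanh(e))
}
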
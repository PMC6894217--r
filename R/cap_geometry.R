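# Pseudo-ellipsoidal and pseudo-spherical cap geometry.
#
# The deformed vesicle is modelled as a cap cut from an ellipsoid of
# revolution (equatorial semi-axis a, polar semi-axis b, axis ratio
# eps_r = b/a) or, in the eps_r = 1 limit, from a sphere of radius R.
# Because the reported cap height h does not by itself conserve the vesicle
# volume, the height entering the volume and contact-angle formulas is the
# effective height u = m*h, with m a dimensionless correction parameter
# determined by volume conservation.
#
# Coordinate convention: the generating ellipse is centred at the origin with
# the apex at z = +b; the cap occupies z in [b - u, b] and the substrate
# plane is identified with z = b - u.

#' Construct a cap model
#'
#' Bundles the geometric parameters of one deformed-cap family.
#'
#' @param kind `"ellipsoid"` or `"sphere"`.
#' @param a_um Equatorial semi-axis (sphere: the radius R), um.
#' @param b_um Polar semi-axis, um; forced equal to `a_um` for a sphere.
#' @param u_um Effective cap height u = m*h, um.
#' @param h_um Reported cap height h, um; the correction parameter is
#'   `m = u/h`.
#' @return A list of class `cap_model` with fields `kind`, `a_um`, `b_um`,
#'   `eps_r`, `u_um`, `h_um`, `m`.
#' @export
cap_model <- function(kind = c("ellipsoid", "sphere"), a_um, b_um = a_um,
                      u_um, h_um) {
  kind <- match.arg(kind)
  if (kind == "sphere") b_um <- a_um
  stopifnot(a_um > 0, b_um > 0, b_um <= a_um, u_um > 0, h_um > 0)
  structure(
    list(kind = kind, a_um = a_um, b_um = b_um, eps_r = b_um / a_um,
         u_um = u_um, h_um = h_um, m = u_um / h_um),
    class = "cap_model"
  )
}

#' @export
print.cap_model <- function(x, ...) {
  cat(sprintf("<cap_model: %s>  a = %.4f um, b = %.4f um (eps_r = %.4f)\n",
              x$kind, x$a_um, x$b_um, x$eps_r))
  cat(sprintf("  h = %.4f um, u = m*h = %.4f um, m = %.4f\n",
              x$h_um, x$u_um, x$m))
  invisible(x)
}

#' Volume of the pseudo cap
#'
#' Volume of a cap of effective height u on an ellipsoid with axis ratio
#' eps_r and contact radius r0:
#' `V = pi*u*(3*r0^2*eps_r^2 + u^2) / (6*eps_r^2)`.
#' With `eps_r = 1` this is the classical spherical-cap volume
#' `pi*u*(3*r0^2 + u^2)/6`.
#'
#' @param u_um Effective height, um (> 0).
#' @param r0_um Contact radius, um (> 0).
#' @param eps_r Axis ratio b/a in (0, 1].
#' @return Volume in um^3.
#' @export
pseudo_cap_volume <- function(u_um, r0_um, eps_r) {
  if (any(u_um <= 0) || any(r0_um <= 0) || any(eps_r <= 0) || any(eps_r > 1)) {
    stop("need u > 0, r0 > 0, eps_r in (0, 1]", call. = FALSE)
  }
  pi * u_um * (3 * r0_um^2 * eps_r^2 + u_um^2) / (6 * eps_r^2)
}

#' Effective cap height from volume conservation
#'
#' Inverts [pseudo_cap_volume()] for u: the unique positive root of the
#' strictly increasing cubic `u^3 + 3*r0^2*eps_r^2*u - 6*V*eps_r^2/pi = 0`.
#' Solved by bracketed root finding and polished by Newton steps to a
#' relative volume residual below 1e-12.
#'
#' @param V_um3 Conserved cap volume, um^3 (> 0).
#' @param r0_um Contact radius, um (> 0).
#' @param eps_r Axis ratio b/a in (0, 1].
#' @return Effective height u in um.
#' @export
solve_effective_height <- function(V_um3, r0_um, eps_r) {
  stopifnot(V_um3 > 0, r0_um > 0, eps_r > 0, eps_r <= 1)
  k <- 3 * r0_um^2 * eps_r^2
  d <- 6 * V_um3 * eps_r^2 / pi
  g <- function(u) u^3 + k * u - d
  hi <- (6 * V_um3 / pi)^(1 / 3) + 3 * r0_um
  u <- stats::uniroot(g, c(0, hi), tol = .Machine$double.eps^0.75)$root
  for (i in 1:4) u <- u - g(u) / (3 * u^2 + k)  # Newton polish
  stopifnot(abs(pseudo_cap_volume(u, r0_um, eps_r) - V_um3) / V_um3 < 1e-12)
  u
}

#' Contact angle of the pseudo-ellipsoidal cap
#'
#' From the slope of the ellipse at the contact line with the corrected
#' height: `tan(theta0) = eps_r^2 * r0 / (b - u)`. Computed as
#' `atan2(eps_r^2 * r0, b - u)`, giving the principal value in (0, pi):
#' acute when u < b, exactly pi/2 when u = b, obtuse when u > b.
#'
#' @param r0_um Contact radius, um (> 0).
#' @param b_um Polar semi-axis, um (> 0).
#' @param u_um Effective height, um (> 0).
#' @param eps_r Axis ratio b/a.
#' @return Contact angle theta0 in radians.
#' @export
contact_angle_ellipsoid <- function(r0_um, b_um, u_um, eps_r) {
  stopifnot(r0_um > 0, b_um > 0, u_um > 0, eps_r > 0)
  atan2(eps_r^2 * r0_um, b_um - u_um)
}

#' Contact angle of the pseudo-spherical cap
#'
#' From the half-angle relation `u = r0 * tan(theta0/2)`:
#' `theta0 = 2*atan(u/r0)`, the principal value in (0, pi), obtuse whenever
#' u > r0. For an obtuse angle the supplement `pi - theta0` is the angle a
#' goniometer reading below 90 degrees would report; downstream force-balance
#' computations always consume the principal value.
#'
#' @param r0_um Contact radius, um (> 0).
#' @param u_um Effective height, um (> 0).
#' @return Contact angle theta0 in radians.
#' @export
contact_angle_sphere <- function(r0_um, u_um) {
  stopifnot(r0_um > 0, u_um > 0)
  2 * atan(u_um / r0_um)
}

#' Cap volume from contact radius, height and contact angle
#'
#' The three-parameter cap volume
#' `V = pi*r0*h/3 * (2*r0*tan(theta0) - h)/tan(theta0)`.
#' Provided as a cross-check against [pseudo_cap_volume()]: with the raw
#' (uncorrected) height the two disagree, which is precisely why the
#' correction parameter m is introduced.
#'
#' @param r0_um Contact radius, um.
#' @param h_um Cap height, um.
#' @param theta0 Contact angle, radians, not 0 or pi.
#' @return Volume in um^3.
#' @export
cap_volume_from_angle <- function(r0_um, h_um, theta0) {
  t <- tan(theta0)
  if (!is.finite(t) || t == 0) {
    stop("theta0 must not be 0 or pi (tan(theta0) = 0)", call. = FALSE)
  }
  pi * r0_um * h_um / 3 * (2 * r0_um * t - h_um) / t
}

#' Lateral area of an ellipsoidal zone
#'
#' Integrates the differential area of the ellipsoid of revolution,
#' `dA = (2*pi*a/b^2) * sqrt(b^4 + (a^2 - b^2) z^2) dz`,
#' between two z-limits by adaptive quadrature (relative tolerance 1e-10).
#' With a = b this reduces to Archimedes' theorem: the zone area 2*pi*R*dz.
#'
#' @param a_um Equatorial semi-axis, um (a >= b).
#' @param b_um Polar semi-axis, um.
#' @param z_lo_um,z_hi_um Integration limits, um, with
#'   `-b <= z_lo < z_hi <= b`.
#' @return Area in um^2.
#' @export
ellipsoid_cap_area <- function(a_um, b_um, z_lo_um, z_hi_um) {
  stopifnot(a_um >= b_um, b_um > 0)
  if (z_lo_um < -b_um || z_hi_um > b_um || z_lo_um >= z_hi_um) {
    stop("need -b <= z_lo < z_hi <= b", call. = FALSE)
  }
  f <- function(z) (2 * pi * a_um / b_um^2) *
    sqrt(b_um^4 + (a_um^2 - b_um^2) * z^2)
  stats::integrate(f, z_lo_um, z_hi_um, rel.tol = 1e-10,
                   subdivisions = 200L)$value
}

#' Area of a spherical cap of effective height u
#'
#' `A = 2*pi*R*u` (Archimedes).
#'
#' @param R_um Sphere radius, um (> 0).
#' @param u_um Effective height, um (> 0).
#' @return Area in um^2.
#' @export
sphere_cap_area <- function(R_um, u_um) {
  stopifnot(R_um > 0, u_um > 0)
  2 * pi * R_um * u_um
}

#' Inclination of the fitted locus at radius r
#'
#' The inclination theta between the membrane tangent line and the radial
#' direction follows from the locus slope `dz/dr = -tan(theta)`:
#' `theta(r) = atan(b*r / (a*sqrt(a^2 - r^2)))`, zero at the apex and
#' approaching 90 degrees at the equator. Strictly increasing in r.
#'
#' @param fit A `locus_fit` (either family), or a list with `a_um`, `b_um`.
#' @param r_um Radial station(s), um, in `[0, a)`.
#' @return Inclination in radians (vectorised over `r_um`).
#' @export
inclination_profile <- function(fit, r_um) {
  a <- fit$a_um
  b <- fit$b_um
  if (any(r_um < 0) || any(r_um >= a)) {
    stop("r must lie in [0, a)", call. = FALSE)
  }
  atan(b * r_um / (a * sqrt(a^2 - r_um^2)))
}
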
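# Closed-form membrane-tension fields along the free membrane, the general
# semi-inverse tension formula for an arbitrary axisymmetric shape, and a
# residual checker for the raw equilibrium equations.
#
# The membrane carries an isotropic tension f(r) set by the hydrostatic
# interior pressure p(z) = p0 - rho*g*z acting on the assumed cap shape.
# For the two cap families the field has a closed form; for an arbitrary
# differentiable shape z(r) the semi-inverse quotient applies away from the
# apex, where it is singular (0/0) and is handled by limit extrapolation.

#' Membrane tension field of the pseudo-ellipsoidal cap
#'
#' Closed-form meridional tension at radial station r on an ellipsoidal cap
#' (semi-axes a, b, correction parameter m) under basal pressure p0 and
#' liquid weight density rho*g:
#' \deqn{f = \frac{\sqrt{Q}\,[p_0 Q - \rho g a b m (a^2-r^2)^{3/2}]}
#'            {b\,(Q + a^4 m^2)},\quad Q = a^4m^2 - a^2m^2r^2 + b^2r^2.}
#' At the apex (r = 0) this reduces to `a^2 (p0*m - rho*g*b) / (2b)`; with
#' m = 1 and g = 0 that is the classical apex tension `p0*a^2/(2b)` of an
#' ellipsoidal shell under uniform pressure.
#'
#' @param r_um Radial station(s), um, in `[0, a)` (vectorised).
#' @param a_um Equatorial semi-axis, um.
#' @param b_um Polar semi-axis, um.
#' @param m Dimensionless height-correction parameter.
#' @param p0_Pa Basal pressure, Pa.
#' @param rho_kg_per_m3 Liquid density, kg/m^3.
#' @param g_m_per_s2 Gravitational acceleration, m/s^2.
#' @return Membrane tension in N/m.
#' @export
tension_ellipsoid <- function(r_um, a_um, b_um, m, p0_Pa,
                              rho_kg_per_m3 = 1000, g_m_per_s2 = 9.8) {
  stopifnot(a_um > 0, b_um > 0, m > 0)
  if (any(r_um < 0) || any(r_um >= a_um)) {
    stop("r must lie in [0, a)", call. = FALSE)
  }
  a <- a_um * .UM; b <- b_um * .UM; r <- r_um * .UM
  Q <- a^4 * m^2 - a^2 * m^2 * r^2 + b^2 * r^2
  grav <- rho_kg_per_m3 * g_m_per_s2 * a * b * m * (a^2 - r^2)^(3 / 2)
  sqrt(Q) * (p0_Pa * Q - grav) / (b * (a^4 * m^2 + Q))
}

#' Membrane tension field of the pseudo-spherical cap
#'
#' The b = a limit of [tension_ellipsoid()]:
#' \deqn{f = \frac{\sqrt{a^2m^2 - m^2r^2 + r^2}\,
#'            [p_0(a^4m^2 - a^2m^2r^2 + a^2r^2)
#'             - \rho g a^2 m (a^2-r^2)^{3/2}]}
#'            {2a^4m^2 - a^2m^2r^2 + a^2r^2}.}
#' At the apex it reduces to `a*(p0*m - rho*g*a)/2`; with m = 1 and g = 0
#' it is the uniform Laplace tension `p0*a/2` at every r.
#'
#' @param r_um Radial station(s), um, in `[0, a)` (vectorised).
#' @param a_um Sphere radius R, um.
#' @param m Dimensionless height-correction parameter.
#' @param p0_Pa Basal pressure, Pa.
#' @param rho_kg_per_m3 Liquid density, kg/m^3.
#' @param g_m_per_s2 Gravitational acceleration, m/s^2.
#' @return Membrane tension in N/m.
#' @export
tension_sphere <- function(r_um, a_um, m, p0_Pa,
                           rho_kg_per_m3 = 1000, g_m_per_s2 = 9.8) {
  stopifnot(a_um > 0, m > 0)
  if (any(r_um < 0) || any(r_um >= a_um)) {
    stop("r must lie in [0, a)", call. = FALSE)
  }
  a <- a_um * .UM; r <- r_um * .UM
  s <- sqrt(a^2 * m^2 - m^2 * r^2 + r^2)
  Q <- a^4 * m^2 - a^2 * m^2 * r^2 + a^2 * r^2
  grav <- rho_kg_per_m3 * g_m_per_s2 * a^2 * m * (a^2 - r^2)^(3 / 2)
  s * (p0_Pa * Q - grav) / (a^4 * m^2 + Q)
}

#' Semi-inverse membrane tension for an arbitrary axisymmetric shape
#'
#' Given a differentiable meridian z(r) (height above the substrate, z' < 0
#' on the free cap so the inclination is positive), evaluates the tension
#' that balances the hydrostatic pressure on that shape:
#' \deqn{f = \frac{p/\tan\theta - p z' + p' z}
#'            {\theta'\cos^2\theta/\sin\theta + \theta'\sin\theta + s'/r}}
#' with `theta = atan(-z')`, `theta' = -z'' / (1 + z'^2)`,
#' `p = p0 - rho*g*z`, `p' = -rho*g*z'` and the meridian arc-length
#' derivative `s' = 1/cos(theta)`. Singular at the apex (r = 0); evaluate
#' at r > 0 and recover the apex by limiting values.
#'
#' @param z_fun,dz_fun,d2z_fun Functions of r (um) returning z (um),
#'   z' (dimensionless) and z'' (1/um).
#' @param r_um Radial station(s), um, strictly positive (vectorised).
#' @param p0_Pa Basal pressure, Pa.
#' @param rho_kg_per_m3 Density, kg/m^3.
#' @param g_m_per_s2 Gravitational acceleration, m/s^2.
#' @return Membrane tension in N/m.
#' @export
tension_general <- function(z_fun, dz_fun, d2z_fun, r_um, p0_Pa,
                            rho_kg_per_m3 = 1000, g_m_per_s2 = 9.8) {
  if (any(r_um <= 0)) stop("r must be strictly positive (apex is singular)",
                           call. = FALSE)
  r <- r_um * .UM
  z <- z_fun(r_um) * .UM
  zp <- dz_fun(r_um)                 # dimensionless
  zpp <- d2z_fun(r_um) / .UM         # 1/m
  if (any(zp >= 0)) stop("z'(r) must be negative on the free cap",
                         call. = FALSE)
  theta <- atan(-zp)
  thetap <- -zpp / (1 + zp^2)
  p <- p0_Pa - rho_kg_per_m3 * g_m_per_s2 * z
  pp <- -rho_kg_per_m3 * g_m_per_s2 * zp
  sp <- 1 / cos(theta)
  num <- p / tan(theta) - p * zp + pp * z
  den <- thetap * cos(theta)^2 / sin(theta) + thetap * sin(theta) + sp / r
  num / den
}

#' Residuals of the raw axisymmetric equilibrium equations
#'
#' Evaluates left-hand side minus right-hand side of the two equilibrium
#' differential equations of the membrane at radius r, for a supplied shape
#' z(r), tension field f(r) and pressure law:
#'
#' * radial: `f/r - f*tan(theta)*theta' - f*s'/(r*cos(theta)) + f'
#'   - (p*z' - p'*z)/cos(theta)`
#' * vertical: `f*theta' + (f/r)*tan(theta) + f'*tan(theta) - p/cos(theta)`
#'
#' A consistent (shape, tension, pressure) triple makes both vanish; for
#' inconsistent inputs the residuals quantify the imbalance, which is their
#' purpose. `f'` is taken by central finite difference with step
#' `1e-4 * r` unless an analytic derivative is supplied.
#'
#' @param z_fun,dz_fun,d2z_fun Shape functions as in [tension_general()].
#' @param f_fun Tension field, function of r (um) returning N/m.
#' @param r_um Radial station, um, strictly positive.
#' @param p0_Pa,rho_kg_per_m3,g_m_per_s2 Pressure-law parameters.
#' @param df_fun Optional analytic derivative of the tension field,
#'   function of r (um) returning N/m per um.
#' @return Named numeric vector `c(residual_r, residual_z)` in Pa.
#' @export
equilibrium_residuals <- function(z_fun, dz_fun, d2z_fun, f_fun, r_um,
                                  p0_Pa, rho_kg_per_m3 = 1000,
                                  g_m_per_s2 = 9.8, df_fun = NULL) {
  stopifnot(r_um > 0)
  r <- r_um * .UM
  z <- z_fun(r_um) * .UM
  zp <- dz_fun(r_um)
  zpp <- d2z_fun(r_um) / .UM
  theta <- atan(-zp)
  thetap <- -zpp / (1 + zp^2)
  p <- p0_Pa - rho_kg_per_m3 * g_m_per_s2 * z
  pp <- -rho_kg_per_m3 * g_m_per_s2 * zp
  sp <- 1 / cos(theta)
  f <- f_fun(r_um)
  if (is.null(df_fun)) {
    dr <- 1e-4 * r_um
    fp <- (f_fun(r_um + dr) - f_fun(r_um - dr)) / (2 * dr) / .UM
  } else {
    fp <- df_fun(r_um) / .UM
  }
  res_r <- f / r - f * tan(theta) * thetap - f * sp / (r * cos(theta)) + fp -
    (p * zp - pp * z) / cos(theta)
  res_z <- f * thetap + (f / r) * tan(theta) + fp * tan(theta) -
    p / cos(theta)
  c(residual_r = res_r, residual_z = res_z)
}

#' Sampled tension profile along the free membrane
#'
#' Samples the closed-form tension field of a cap model at `n_points`
#' radial stations uniformly spaced on `[0, r0]`, together with the
#' cap-frame height `z = b*sqrt(1 - r^2/a^2)` (generating ellipse centred
#' at the origin, apex at z = +b, substrate plane at z = b - u), the
#' inclination, and the hydrostatic pressure at the height above the
#' substrate.
#'
#' @param model A [cap_model()].
#' @param eq An `equilibrium_state` from [run_chain()] (supplies r0 and p0).
#' @param params A [material_params()] object (supplies rho and g).
#' @param n_points Number of radial stations (>= 2).
#' @return A `data.frame` of class `tension_profile` with columns `r_um`,
#'   `z_um`, `theta_deg`, `p_Pa`, `f_mN_per_m`.
#' @export
profile_table <- function(model, eq, params, n_points = 101L) {
  stopifnot(inherits(model, "cap_model"),
            inherits(eq, "equilibrium_state"),
            inherits(params, "material_params"), n_points >= 2)
  r <- seq(0, eq$r0_um, length.out = n_points)
  z <- model$b_um * sqrt(pmax(0, 1 - r^2 / model$a_um^2))
  theta <- inclination_profile(model, r)
  z_above <- pmax(0, z - (model$b_um - model$u_um))
  p <- hydrostatic_pressure(eq$p0_Pa, params$rho_kg_per_m3,
                            params$g_m_per_s2, z_above)
  f <- if (model$kind == "sphere") {
    tension_sphere(r, model$a_um, model$m, eq$p0_Pa,
                   params$rho_kg_per_m3, params$g_m_per_s2)
  } else {
    tension_ellipsoid(r, model$a_um, model$b_um, model$m, eq$p0_Pa,
                      params$rho_kg_per_m3, params$g_m_per_s2)
  }
  out <- data.frame(r_um = r, z_um = z, theta_deg = theta * 180 / pi,
                    p_Pa = p, f_mN_per_m = f * 1e3)
  class(out) <- c("tension_profile", "data.frame")
  out
}

#' Write a tension profile as CSV
#'
#' Columns `r_um,z_um,theta_deg,p_Pa,f_mN_per_m` at 10 significant digits.
#'
#' @param profile A `tension_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "tension_profile"))
  df <- as.data.frame(lapply(profile, function(col) {
    if (is.numeric(col)) signif(col, 10) else col
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
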
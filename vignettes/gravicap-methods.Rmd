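---
title: "Methods: the gravity-loaded vesicle cap model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the gravity-loaded vesicle cap model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gravicap)
```

## The model

A vesicle is idealised as a water sac: an incompressible liquid interior
wrapped in a thin, closed, isotropic, linearly elastic membrane. Resting on a
rigid substrate under its own weight, the sac settles into an axisymmetric
cap with a circular contact patch of radius $r_0$. The membrane carries an
in-plane tension $f$ (force per unit length) that balances the hydrostatic
interior pressure

$$p(z) = p_0 - \rho g z,$$

where $p_0$ is the basal pressure at the substrate plane and $z$ the height
above it. Force balance of an axisymmetric membrane element in the radial and
vertical directions gives two coupled first-order equations in $f(r)$,
$\theta(r)$ (the inclination between the membrane tangent and the radial
direction, with $dz/dr = -\tan\theta$) and $p$. The package solves them
semi-inversely: the cap *shape* is assumed (fitted to morphometry), and the
tension field that balances the pressure on that shape follows in closed
form.

Two shape families are supported:

* **pseudo-ellipsoidal cap** — the meridian is an ellipse
  $r^2/a^2 + z^2/b^2 = 1$ with equatorial semi-axis $a$ and polar semi-axis
  $b$ (axis ratio $\varepsilon_r = b/a$);
* **pseudo-spherical cap** — the $\varepsilon_r = 1$ limit, a circle of
  radius $R$.

"Pseudo" refers to the height correction: the measured cap height $h$ does
not by itself conserve the vesicle volume $V$, so the height entering the
volume and contact-angle formulas is an *effective* height $u = mh$, with
$m$ a dimensionless correction parameter fixed by volume conservation,

$$V = \frac{\pi u}{6\varepsilon_r^2}\left[3 r_0^2 \varepsilon_r^2 + u^2\right].$$

### The solved chain

`run_chain()` executes the scalar chain for one branch:

1. **Locus fit.** Contact radii $r_0 = \sqrt{A/\pi}$ from the measured
   bottom areas; ordinary least squares of $h^2$ on $r_0^2$ yields
   $b^2 = c_0$ and $a^2 = -c_0/c_1$ from the line $h^2 = c_0 + c_1 r_0^2$
   (for the circle, $R^2 = \overline{r_0^2 + h^2}$).
2. **Adhesive contact.** The contact radius of the settled sac is set by
   JKR adhesion of a soft sphere of equivalent radius $R_0 = (3V/4\pi)^{1/3}$:
   $r_0^3 = 9\pi(1-\nu^2) R_0^2 \Gamma / (2E)$, with adhesion energy
   $\Gamma$, Young's modulus $E$ and Poisson ratio $\nu$. An energy audit
   (`energy_ratio()`) confirms the surface term dominates bending and
   gravitational contributions, which is what licenses the JKR treatment.
3. **Effective height.** The unique positive root of the strictly
   increasing cubic $u^3 + 3 r_0^2 \varepsilon_r^2 u - 6 V \varepsilon_r^2/\pi = 0$.
4. **Contact angle.** Ellipsoid: $\tan\theta_0 = \varepsilon_r^2 r_0/(b-u)$,
   taken as the principal value of $\operatorname{atan2}$ in $(0,\pi)$.
   Sphere: $\theta_0 = 2\arctan(u/r_0)$.
5. **Wetting balance.** $F_0 = \Gamma/(1-\cos\theta_0)$.
6. **Global force balance.** The whole membrane pulls on the contact line
   against the pressurised base and the liquid weight $G=\rho g V$:
   $2\pi r_0 F_0 \sin\theta_0 = \pi r_0^2 p_0 - G$, solved for $p_0$.

Both boundary conditions therefore hold on every solved state by
construction; the test suite verifies the round trip to $10^{-10}$
relative.

### The tension fields

With the shape and $p_0$ fixed, the closed forms `tension_ellipsoid()` and
`tension_sphere()` give $f(r)$ on $[0, a)$. Useful limits, all asserted in
the tests:

* at $a = b$ the ellipsoidal field reduces *algebraically* to the spherical
  one (checked to $10^{-12}$ over random parameters);
* with $m = 1,\, g = 0$ the spherical field is the uniform Laplace tension
  $p_0 a/2$, and the ellipsoidal apex tension is $p_0 a^2/(2b)$, the
  classical pressurised-shell results;
* `tension_general()` evaluates the semi-inverse quotient for *any*
  differentiable meridian and recovers $p_0 R/2$ exactly on the weightless
  sphere, and `equilibrium_residuals()` confirms the raw radial and vertical
  equations vanish there.

## Parameters

| parameter | meaning | unit | default |
|---|---|---|---|
| `gamma_J_per_m2` | adhesion energy per unit area $\Gamma$ | J/m² | 6e-4 |
| `E_Pa` | membrane Young's modulus | Pa | 1000 |
| `nu` | Poisson ratio | — | 0.3 |
| `rho_kg_per_m3` | liquid density | kg/m³ | 1000 |
| `g_m_per_s2` | gravitational acceleration | m/s² | 9.8 |
| `V_um3` | conserved vesicle volume | μm³ | 3000 |
| `R0_um` | equivalent suspended-sphere radius | μm | 8.9 |
| `kappa_J` | bending modulus (~20 kT) | J | 1e-19 |
| `t_um` | membrane thickness (carried, unused) | μm | 0.1 |
| `h_ellipsoid_um` | reported cap height, ellipsoid branch | μm | 13.29 |
| `h_sphere_um` | reported cap height, sphere branch | μm | 13.02 |

The defaults describe a ~3000 μm³ vesicle settling in water under
terrestrial gravity; `g_m_per_s2 = 0` is the microgravity limit and
multiples of 9.8 model hypergravity. The conserved volume is taken as
3000 μm³ exactly rather than any single measured row (the five measured
volumes scatter within 0.5% of it); this convention moves the solved contact
angle by well under 0.2%.

## Design choices where the design was open

* **Regression direction.** Fitting $h^2$ on $r_0^2$ (not the reverse, and
  not orthogonal distance) is normative: it is the direction that reproduces
  the reference semi-axes to four significant figures. The reverse direction
  does not.
* **Residual and variance convention.** Residuals are measured in the
  height direction, $h_{\text{obs}} - b\sqrt{1 - r_0^2/a^2}$, and the
  variance uses divisor $n$. Only the *ordering* of the two family variances
  is meaningful (ellipse < circle on the packaged table); absolute values
  depend on this convention.
* **Contact-angle branch.** Angles are principal values in $(0,\pi)$. The
  ellipsoid branch is acute (≈73.6°); the sphere branch is obtuse (≈117.4°),
  and its supplement (≈62.6°) is what a below-90° goniometer convention
  would report. Both are emitted, but the *principal* value is always the
  one consumed by the wetting and force balances — the only choice for which
  the solved $F_0$ and $p_0$ of the two branches are mutually consistent.
* **The $u = mh$ split.** Volume conservation determines only the product
  $u = mh$. No geometric relation we tested (ellipse height at $r_0$,
  area-conserving height, cylinder-equivalent height) recovers the reported
  branch heights, so $h$ is a configuration input (defaults above) and
  $m := u/h$ is derived.
* **Arc-length derivative.** $s' = 1/\cos\theta$ (meridian arc length,
  $ds = dr/\cos\theta$).
* **Substrate plane.** The generating ellipse is centred at the origin with
  the apex at $z = +b$; the substrate is identified with $z = b - u$.
  Profile tables report the ellipse-frame $z$ and key the field primarily to
  $r$.

## Numerical choices

* The volume cubic is solved by bracketed root finding on
  $[0, (6V/\pi)^{1/3} + 3r_0]$ plus Newton polishing; the accepted root
  reproduces the volume to $10^{-12}$ relative. Deterministic.
* The ellipsoidal zone area uses adaptive quadrature at relative tolerance
  $10^{-10}$; it matches the closed-form oblate-spheroid area to machine
  precision.
* The semi-inverse quotient is singular at the apex ($1/r$ and
  $1/\tan\theta$); `tension_general()` refuses $r = 0$, and profiles report
  the closed-form apex value instead.
* In the residual checker $f'$ defaults to a central difference with step
  $10^{-4} r$; an analytic derivative can be supplied.
* Predicted locus heights at $r_0 \ge a$ are clamped to zero with a warning
  rather than erroring, so a fit can still report residuals for outlying
  points.

## The synthetic generator

`generate_synthetic_states()` emulates a measured spreading series: contact
radii evenly spaced over the observed range (defaults 6.3–14.9 μm), heights
on an exact ellipse locus (defaults $a = 16.67$, $b = 15.90$ μm) plus
additive Gaussian measurement noise, and a constant-volume column. The
default noise of 0.1 μm reflects optical height-measurement precision at
this scale. What it deliberately does *not* emulate: correlated errors
between area and height (both are derived from the same images in practice),
volume drift during spreading, contact-line pinning, or any non-elliptical
shape relaxation. Passing recovery tests therefore demonstrates estimator
correctness under the stated error model, not robustness to real imaging
artefacts.

Problem sizes throughout the suite are desk-scale: five-point reference
fits, 50-point synthetic recovery series, 101-point tension profiles — the
whole analysis chain runs in well under a second.

## Known limitations

* **Apex gravity trend.** Re-solving the chain over $g$ raises $p_0$
  strictly and raises the tension at the contact line, but the *apex*
  tension falls very weakly with $g$: the direct weight term
  $\rho g b$ in the field slightly outweighs the induced rise $m\,dp_0/dg$
  there. Gravity-monotonicity of the field is therefore asserted at the
  contact line, not pointwise.
* **Field maxima.** With the default parameters the closed-form fields are
  nearly flat on $[0, r_0]$ (ellipsoid: 1.63–1.69 mN/m; sphere:
  0.72–0.75 mN/m), with the maximum at the apex. Reported peak tensions
  about twice these values are not recoverable from the printed closed forms
  on any radial interval; the package asserts only formula-level facts.
* **Energy-ratio magnitude.** The transparent term-by-term energy audit
  gives a surface-to-(elastic+gravity) ratio of order 1 against the
  membrane-stretch term and order $10^2$–$10^3$ against bending and gravity
  alone — not the conventionally quoted $10^8$. The adhesion-dominated
  (JKR) treatment is retained because the surface term does dominate the
  bending and gravitational terms; `energy_ratio()` warns about the
  magnitude discrepancy rather than hiding it.
* The membrane is treated as a tension-carrying surface: no bending
  (Helfrich) corrections, no finite-thickness shell elasticity ($t$ is
  carried but unused), no contact-line pinning, no dynamics of spreading.

## A worked run

```{r}
report <- reproduce_paper()
report
```

Everything printed above is computed at run time from the packaged
five-state table and the default material parameters.
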
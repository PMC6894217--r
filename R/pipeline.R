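# Orchestration: state-table I/O, synthetic-state generation, the solved
# adhesion/equilibrium chain for each cap branch, and the one-command
# end-to-end reproduction of the reference analysis.

STATES_HEADER <- c("state_id", "bottom_area_um2", "height_um", "volume_um3")

#' Read a spreading-state table from CSV
#'
#' Expects the exact header `state_id,bottom_area_um2,height_um,volume_um3`
#' (comma-separated, UTF-8; lines starting with `#` are ignored). Row order
#' is preserved. Malformed files raise a schema error naming the offending
#' row and column.
#'
#' @param path Path to the CSV file.
#' @return A `spreading_states` table.
#' @export
read_states <- function(path) {
  if (!file.exists(path)) {
    stop(errorCondition(paste0("states file not found: ", path),
                        class = c("gravicap_schema_error", "error")))
  }
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character", fileEncoding = "UTF-8"),
    error = function(e) {
      stop(errorCondition(paste0("cannot parse states CSV: ",
                                 conditionMessage(e)),
                          class = c("gravicap_schema_error", "error")))
    }
  )
  if (!identical(names(df), STATES_HEADER)) {
    stop(errorCondition(
      paste0("states CSV header must be exactly: ",
             paste(STATES_HEADER, collapse = ","), "; got: ",
             paste(names(df), collapse = ",")),
      class = c("gravicap_schema_error", "error")))
  }
  if (nrow(df) == 0) {
    stop(errorCondition("states CSV has no data rows",
                        class = c("gravicap_schema_error", "error")))
  }
  for (col in STATES_HEADER[-1]) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad) > 0) {
      stop(errorCondition(
        sprintf("non-numeric or non-positive value in column '%s', row %d",
                col, bad[1]),
        class = c("gravicap_schema_error", "error")))
    }
    df[[col]] <- v
  }
  spreading_states(df$state_id, df$bottom_area_um2, df$height_um,
                   df$volume_um3)
}

#' Write a spreading-state table to CSV
#'
#' Inverse of [read_states()] (the derived `r0_um` column is not written).
#'
#' @param states A `spreading_states` table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_states <- function(states, path) {
  states <- as_states(states)
  utils::write.csv(as.data.frame(states)[, STATES_HEADER], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate synthetic spreading states on a noisy ellipse locus
#'
#' Emulates a measured spreading series: contact radii evenly spaced in
#' `r0_range`, heights on the exact ellipse locus
#' `h = b_true * sqrt(1 - r0^2/a_true^2)` plus additive Gaussian noise,
#' bottom areas `pi*r0^2`, and a constant volume column. Defaults mirror the
#' reference series: five states with contact radii spanning 6.3-14.9 um on
#' the a = 16.67, b = 15.90 um locus, conserved volume 3000 um^3, and a
#' 0.1 um height-measurement noise.
#'
#' @param a_true,b_true True ellipse semi-axes, um.
#' @param n_states Number of states (>= 3).
#' @param r0_range Length-2 range of contact radii, um, within `(0, a_true)`.
#' @param noise_sd Gaussian height-noise standard deviation, um (>= 0).
#' @param volume_um3 Constant volume column, um^3.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A `spreading_states` table.
#' @export
generate_synthetic_states <- function(a_true = 16.67, b_true = 15.90,
                                      n_states = 5L,
                                      r0_range = c(6.3, 14.9),
                                      noise_sd = 0.1, volume_um3 = 3000,
                                      seed = 1L) {
  stopifnot(a_true > 0, b_true > 0, n_states >= 3, length(r0_range) == 2,
            noise_sd >= 0, volume_um3 > 0)
  if (r0_range[1] <= 0 || r0_range[2] >= a_true || r0_range[1] >= r0_range[2]) {
    stop("r0_range must lie within (0, a_true) and be increasing",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  r0 <- seq(r0_range[1], r0_range[2], length.out = n_states)
  h <- b_true * sqrt(1 - r0^2 / a_true^2) + stats::rnorm(n_states, 0, noise_sd)
  if (any(h <= 0)) {
    stop("noise produced a non-positive height; lower noise_sd", call. = FALSE)
  }
  spreading_states(
    state_id = sprintf("s%02d", seq_len(n_states)),
    bottom_area_um2 = pi * r0^2,
    height_um = h,
    volume_um3 = rep(volume_um3, n_states)
  )
}

#' Solve the full adhesion/equilibrium chain for one cap branch
#'
#' Executes the scalar chain of the model: fit the branch locus to the
#' states (ellipse or circle), take the contact radius from JKR adhesive
#' contact, solve the volume-conservation cubic for the effective height u,
#' form the branch contact angle, apply Young's wetting equation for the
#' bottom tension F0, compute the liquid weight G and the basal pressure p0
#' from the global force balance, and split u into the correction parameter
#' m = u/h using the configured branch height h.
#'
#' The returned state satisfies both boundary conditions by construction:
#' `2*pi*r0*F0*sin(theta0) = pi*r0^2*p0 - G` and
#' `Gamma = F0*(1 - cos(theta0))`.
#'
#' @param states A `spreading_states` table (or compatible data.frame).
#' @param params A [material_params()] object.
#' @param branch `"ellipsoid"` or `"sphere"`.
#' @return A list of class `equilibrium_state` with the locus fit, the cap
#'   model, and fields `r0_um`, `u_um`, `m`, `h_um`, `theta0_rad`,
#'   `theta0_deg`, `theta0_supplement_deg`, `G_N`, `F0_N_per_m`,
#'   `F0_mN_per_m`, `p0_Pa`.
#' @export
run_chain <- function(states, params = material_params(),
                      branch = c("ellipsoid", "sphere")) {
  branch <- match.arg(branch)
  stopifnot(inherits(params, "material_params"))
  states <- as_states(states)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  fit <- stage("locus_fit", if (branch == "ellipsoid") {
    fit_ellipse_locus(states)
  } else {
    fit_circle_locus(states)
  })
  eps_r <- fit$b_um / fit$a_um
  r0 <- stage("jkr_contact_radius", jkr_contact_radius(params))
  u <- stage("solve_effective_height",
             solve_effective_height(params$V_um3, r0, eps_r))
  theta0 <- stage("contact_angle", if (branch == "ellipsoid") {
    contact_angle_ellipsoid(r0, fit$b_um, u, eps_r)
  } else {
    contact_angle_sphere(r0, u)
  })
  F0 <- stage("young_tension", young_tension(params$gamma_J_per_m2, theta0))
  G <- stage("gravity_load", gravity_load(params))
  p0 <- stage("basal_pressure", basal_pressure(r0, F0, theta0, G))
  h_cfg <- if (branch == "ellipsoid") params$h_ellipsoid_um else
    params$h_sphere_um
  model <- cap_model(kind = if (branch == "ellipsoid") "ellipsoid" else
                       "sphere",
                     a_um = fit$a_um, b_um = fit$b_um, u_um = u, h_um = h_cfg)
  structure(
    list(branch = branch, fit = fit, model = model,
         r0_um = r0, u_um = u, m = model$m, h_um = h_cfg,
         theta0_rad = theta0, theta0_deg = theta0 * 180 / pi,
         theta0_supplement_deg = 180 - theta0 * 180 / pi,
         G_N = G, F0_N_per_m = F0, F0_mN_per_m = F0 * 1e3, p0_Pa = p0),
    class = "equilibrium_state"
  )
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf("<equilibrium_state: %s branch>\n", x$branch))
  cat(sprintf("  r0     = %.4f um (JKR)\n", x$r0_um))
  cat(sprintf("  u      = %.4f um, m = %.4f (h = %.2f um)\n",
              x$u_um, x$m, x$h_um))
  cat(sprintf("  theta0 = %.2f deg (supplement %.2f deg)\n",
              x$theta0_deg, x$theta0_supplement_deg))
  cat(sprintf("  F0     = %.4f mN/m\n", x$F0_mN_per_m))
  cat(sprintf("  p0     = %.2f Pa\n", x$p0_Pa))
  cat(sprintf("  G      = %.4g N\n", x$G_N))
  invisible(x)
}

#' One-command end-to-end reproduction of the reference analysis
#'
#' Runs the whole model on a spreading-state table (the packaged reference
#' table by default): both locus fits and their variance comparison, both
#' solved equilibrium branches, apex tensions from the closed-form fields,
#' sampled tension profiles, and the energy-budget diagnostic. Fully
#' deterministic: rerunning yields an identical report.
#'
#' @param outdir Optional output directory; when given, writes
#'   `fit_ellipse.json`, `fit_circle.json`, `report.json` and the two
#'   profile CSVs there.
#' @param states A `spreading_states` table; default the packaged
#'   reference table.
#' @param params A [material_params()] object.
#' @param n_points Number of stations in each tension profile.
#' @return A list of class `run_report`.
#' @export
reproduce_paper <- function(outdir = NULL, states = reference_states(),
                            params = material_params(), n_points = 101L) {
  states <- as_states(states)
  fit_e <- fit_ellipse_locus(states)
  fit_c <- fit_circle_locus(states)
  comparison <- compare_loci(fit_e, fit_c)
  eq_e <- run_chain(states, params, "ellipsoid")
  eq_s <- run_chain(states, params, "sphere")
  prof_e <- profile_table(eq_e$model, eq_e, params, n_points)
  prof_s <- profile_table(eq_s$model, eq_s, params, n_points)
  apex_e <- tension_ellipsoid(0, fit_e$a_um, fit_e$b_um, eq_e$m, eq_e$p0_Pa,
                              params$rho_kg_per_m3, params$g_m_per_s2)
  apex_s <- tension_sphere(0, fit_c$a_um, eq_s$m, eq_s$p0_Pa,
                           params$rho_kg_per_m3, params$g_m_per_s2)
  budget <- withCallingHandlers(
    energy_ratio(params, eq_s$r0_um, fit_c$a_um, eq_s$u_um,
                 f_N_per_m = 4e-4,
                 dA_um2 = sphere_cap_area(fit_c$a_um, eq_s$u_um) -
                   4 * pi * params$R0_um^2),
    warning = function(w) invokeRestart("muffleWarning")
  )
  report <- structure(
    list(
      params = unclass(params),
      ellipse_fit = fit_e,
      circle_fit = fit_c,
      locus_comparison = comparison,
      ellipsoid_branch = eq_e,
      sphere_branch = eq_s,
      apex_tension_ellipsoid_mN_per_m = apex_e * 1e3,
      apex_tension_sphere_mN_per_m = apex_s * 1e3,
      ellipsoid_profile = prof_e,
      sphere_profile = prof_s,
      energy_budget = budget,
      package_version = as.character(utils::packageVersion("gravicap"))
    ),
    class = "run_report"
  )
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_locus_report(fit_e, file.path(outdir, "fit_ellipse.json"))
    write_locus_report(fit_c, file.path(outdir, "fit_circle.json"))
    write_profile_csv(prof_e, file.path(outdir, "profile_ellipsoid.csv"))
    write_profile_csv(prof_s, file.path(outdir, "profile_sphere.csv"))
    jsonlite::write_json(run_report_summary(report),
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

run_report_summary <- function(report) {
  eq_scalars <- function(eq) {
    list(r0_um = eq$r0_um, u_um = eq$u_um, m = eq$m, h_um = eq$h_um,
         theta0_deg = eq$theta0_deg,
         theta0_supplement_deg = eq$theta0_supplement_deg,
         F0_mN_per_m = eq$F0_mN_per_m, p0_Pa = eq$p0_Pa, G_N = eq$G_N)
  }
  list(
    params = report$params,
    ellipse_fit = list(a_um = report$ellipse_fit$a_um,
                       b_um = report$ellipse_fit$b_um,
                       residual_variance_um2 =
                         report$ellipse_fit$residual_variance_um2),
    circle_fit = list(R_um = report$circle_fit$a_um,
                      residual_variance_um2 =
                        report$circle_fit$residual_variance_um2),
    locus_verdict = report$locus_comparison$verdict,
    ellipsoid_branch = eq_scalars(report$ellipsoid_branch),
    sphere_branch = eq_scalars(report$sphere_branch),
    apex_tension_ellipsoid_mN_per_m =
      report$apex_tension_ellipsoid_mN_per_m,
    apex_tension_sphere_mN_per_m = report$apex_tension_sphere_mN_per_m,
    energy_budget = unclass(report$energy_budget),
    package_version = report$package_version
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("locus fits: ellipse a = %.4f, b = %.4f um | circle R = %.4f um\n",
              x$ellipse_fit$a_um, x$ellipse_fit$b_um, x$circle_fit$a_um))
  cat(sprintf("variance:   ellipse %.4g vs circle %.4g um^2 -> %s\n",
              x$locus_comparison$ellipse_variance_um2,
              x$locus_comparison$circle_variance_um2,
              x$locus_comparison$verdict))
  print(x$ellipsoid_branch)
  print(x$sphere_branch)
  cat(sprintf("apex tensions: %.4f (ellipsoid) / %.4f (sphere) mN/m\n",
              x$apex_tension_ellipsoid_mN_per_m,
              x$apex_tension_sphere_mN_per_m))
  invisible(x)
}
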
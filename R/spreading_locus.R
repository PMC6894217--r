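# Spreading-state tables and cap-locus fitting.
#
# A settling vesicle is observed in a series of spreading states, each
# characterised by its (circular) bottom contact area, its height and its
# (conserved) volume. The contact radius r0 and height h of the states trace
# a locus in the (r, z) plane; the deformed-cap families assume this locus is
# an ellipse r^2/a^2 + z^2/b^2 = 1 (pseudo-ellipsoidal cap) or a circle
# r^2 + z^2 = R^2 (pseudo-spherical cap).

#' Contact radius of a circular contact patch
#'
#' The contact area of the spreading vesicle is assumed circular, so the
#' contact radius follows directly from the measured bottom area.
#'
#' @param bottom_area_um2 Contact area in square micrometres (vectorised).
#' @return Contact radius in micrometres, `sqrt(area / pi)`.
#' @examples
#' contact_radius_from_area(pi)      # unit circle -> 1
#' contact_radius_from_area(125.09)  # ~6.31 um
#' @export
contact_radius_from_area <- function(bottom_area_um2) {
  if (!is.numeric(bottom_area_um2) || any(!is.finite(bottom_area_um2)) ||
      any(bottom_area_um2 <= 0)) {
    stop("bottom_area_um2 must be finite and strictly positive", call. = FALSE)
  }
  sqrt(bottom_area_um2 / pi)
}

#' Construct a spreading-state table
#'
#' @param state_id Character labels for the states.
#' @param bottom_area_um2 Bottom contact areas, um^2 (> 0).
#' @param height_um Cap heights, um (> 0).
#' @param volume_um3 Enclosed volumes, um^3 (> 0).
#' @return A `data.frame` of class `spreading_states` with the four columns
#'   above plus a derived `r0_um` contact-radius column.
#' @export
spreading_states <- function(state_id, bottom_area_um2, height_um, volume_um3) {
  n <- length(state_id)
  if (length(bottom_area_um2) != n || length(height_um) != n ||
      length(volume_um3) != n) {
    stop("all columns must have the same length", call. = FALSE)
  }
  for (nm in c("bottom_area_um2", "height_um", "volume_um3")) {
    v <- get(nm)
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("column '%s' must be finite and strictly positive", nm),
           call. = FALSE)
    }
  }
  out <- data.frame(
    state_id = as.character(state_id),
    bottom_area_um2 = as.numeric(bottom_area_um2),
    height_um = as.numeric(height_um),
    volume_um3 = as.numeric(volume_um3),
    stringsAsFactors = FALSE
  )
  out$r0_um <- contact_radius_from_area(out$bottom_area_um2)
  class(out) <- c("spreading_states", "data.frame")
  out
}

#' The packaged reference spreading-state table
#'
#' Five measured spreading states of a vesicle of conserved volume close to
#' 3000 um^3, shipped as `extdata/table1.csv`.
#'
#' @return A `spreading_states` table with five rows.
#' @export
reference_states <- function() {
  read_states(system.file("extdata", "table1.csv", package = "gravicap",
                          mustWork = TRUE))
}

locus_height <- function(a_um, b_um, r0_um) {
  # locus-predicted height; points at or beyond the equator are clamped to 0
  arg <- 1 - r0_um^2 / a_um^2
  if (any(arg < 0)) {
    warning("contact radius beyond the fitted semi-axis a; ",
            "predicted height clamped to 0", call. = FALSE)
  }
  b_um * sqrt(pmax(0, arg))
}

new_locus_fit <- function(family, a_um, b_um, states) {
  h_pred <- locus_height(a_um, b_um, states$r0_um)
  res <- states$height_um - h_pred
  structure(
    list(
      family = family,
      a_um = a_um,
      b_um = b_um,
      n_points = nrow(states),
      per_point_residuals_um = res,
      residual_ss_um2 = sum(res^2),
      residual_variance_um2 = mean(res^2)
    ),
    class = "locus_fit"
  )
}

#' Fit the ellipse locus to spreading states
#'
#' Fits the ellipse `r0^2/a^2 + h^2/b^2 = 1` to the (contact radius, height)
#' points of the states by ordinary least squares of `h^2` on `r0^2`
#' (the ellipse rearranged as `h^2 = b^2 - (b^2/a^2) r0^2`). The regression
#' direction is part of the model definition: it is the direction that
#' reproduces the reference semi-axes a = 16.67, b = 15.90 um.
#'
#' Residuals are measured in the height direction, `h - b*sqrt(1 - r0^2/a^2)`,
#' and the residual variance uses divisor n (population convention).
#'
#' @param states A `spreading_states` table with at least 3 rows and distinct
#'   contact radii.
#' @return A `locus_fit` with `family = "ellipse"`, semi-axes `a_um`
#'   (equatorial) and `b_um` (polar), per-point residuals, residual sum of
#'   squares and residual variance.
#' @export
fit_ellipse_locus <- function(states) {
  states <- as_states(states)
  if (nrow(states) < 3) {
    stop("ellipse locus fit needs at least 3 states", call. = FALSE)
  }
  if (anyDuplicated(states$r0_um)) {
    stop("contact radii must be distinct", call. = FALSE)
  }
  x <- states$r0_um^2
  y <- states$height_um^2
  cf <- stats::coef(stats::lm.fit(cbind(1, x), y))
  c0 <- cf[[1]]
  c1 <- cf[[2]]
  if (!is.finite(c0) || !is.finite(c1) || c0 <= 0 || c1 >= 0) {
    stop("degenerate fit: locus is not ellipse-like (need c0 > 0, c1 < 0)",
         call. = FALSE)
  }
  new_locus_fit("ellipse", a_um = sqrt(-c0 / c1), b_um = sqrt(c0), states)
}

#' Fit the circle locus to spreading states
#'
#' Least squares for the single parameter R^2 in `h^2 = R^2 - r0^2`, i.e.
#' `R^2 = mean(r0^2 + h^2)`. Residual conventions as in [fit_ellipse_locus()].
#'
#' @param states A `spreading_states` table with at least 1 row.
#' @return A `locus_fit` with `family = "circle"` and `a_um = b_um = R`.
#' @export
fit_circle_locus <- function(states) {
  states <- as_states(states)
  if (nrow(states) < 1) stop("circle locus fit needs at least 1 state",
                             call. = FALSE)
  R <- sqrt(mean(states$r0_um^2 + states$height_um^2))
  new_locus_fit("circle", a_um = R, b_um = R, states)
}

as_states <- function(states) {
  if (inherits(states, "spreading_states")) return(states)
  if (is.data.frame(states)) {
    need <- c("state_id", "bottom_area_um2", "height_um", "volume_um3")
    if (!all(need %in% names(states))) {
      stop("states table must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    return(spreading_states(states$state_id, states$bottom_area_um2,
                            states$height_um, states$volume_um3))
  }
  stop("states must be a spreading_states table or compatible data.frame",
       call. = FALSE)
}

#' Compare the two fitted locus families
#'
#' The family with the smaller height-direction residual variance represents
#' the deformed cap better. On the packaged reference table the ellipse wins.
#'
#' @param ellipse_fit,circle_fit `locus_fit` objects computed on the same
#'   states.
#' @return A list with both residual variances, their difference, and a
#'   `verdict` of `"ellipse"`, `"circle"` or `"tie"`.
#' @export
compare_loci <- function(ellipse_fit, circle_fit) {
  stopifnot(inherits(ellipse_fit, "locus_fit"), inherits(circle_fit, "locus_fit"))
  if (ellipse_fit$n_points != circle_fit$n_points) {
    stop("fits were not computed on the same number of states", call. = FALSE)
  }
  ve <- ellipse_fit$residual_variance_um2
  vc <- circle_fit$residual_variance_um2
  verdict <- if (ve < vc) "ellipse" else if (vc < ve) "circle" else "tie"
  list(
    ellipse_variance_um2 = ve,
    circle_variance_um2 = vc,
    variance_difference_um2 = ve - vc,
    verdict = verdict
  )
}

#' @export
print.locus_fit <- function(x, ...) {
  cat(sprintf("<locus_fit: %s>\n", x$family))
  if (x$family == "circle") {
    cat(sprintf("  R        = %.4f um\n", x$a_um))
  } else {
    cat(sprintf("  a (equatorial) = %.4f um\n", x$a_um))
    cat(sprintf("  b (polar)      = %.4f um\n", x$b_um))
  }
  cat(sprintf("  n points = %d\n", x$n_points))
  cat(sprintf("  residual SS  = %.4g um^2, variance = %.4g um^2\n",
              x$residual_ss_um2, x$residual_variance_um2))
  invisible(x)
}

#' Write a locus-fit report as JSON
#'
#' @param fit A `locus_fit`.
#' @param path Output path for the JSON report.
#' @return `path`, invisibly.
#' @export
write_locus_report <- function(fit, path) {
  stopifnot(inherits(fit, "locus_fit"))
  jsonlite::write_json(
    list(
      family = fit$family,
      a_um = fit$a_um,
      b_um = fit$b_um,
      residuals_um = fit$per_point_residuals_um,
      residual_variance_um2 = fit$residual_variance_um2
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
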
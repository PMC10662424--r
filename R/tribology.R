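## Soft tribology: Hertzian contact mechanics, torque-to-friction
## conversion (mu = M / (R F_N)), Stribeck-curve handling and
## boundary/mixed/hydrodynamic regime segmentation.

#' Hertzian sphere-on-flat contact for a soft elastomer pair
#'
#' Classical Hertz theory with both bodies of the same modulus:
#' effective modulus \eqn{E^* = E / (2(1 - \nu^2))}, contact radius
#' \eqn{a = (3 F R / (4 E^*))^{1/3}}, mean pressure \eqn{F / (\pi a^2)}
#' and peak pressure 1.5 times the mean. The default-style inputs of a
#' mini-traction machine (19 mm PDMS ball, 2.0 N, 2.0 MPa, \eqn{\nu} =
#' 0.5) give a peak pressure of about 200 kPa.
#'
#' @param ball_radius m.
#' @param load N, normal force.
#' @param youngs_modulus Pa, Young's modulus of both bodies.
#' @param poisson_ratio dimensionless, in [0, 0.5] (default 0.5,
#'   incompressible elastomer).
#' @return An object of class `sphere_contact` with elements
#'   `ball_radius`, `load`, `youngs_modulus`, `poisson_ratio`,
#'   `effective_modulus`, `contact_radius`, `mean_pressure`,
#'   `peak_pressure` (SI units).
#' @export
hertz_sphere_contact <- function(ball_radius, load, youngs_modulus,
                                 poisson_ratio = 0.5) {
  check_number(ball_radius, "ball_radius", positive = TRUE)
  check_number(load, "load", nonneg = TRUE)
  check_number(youngs_modulus, "youngs_modulus", positive = TRUE)
  check_number(poisson_ratio, "poisson_ratio", nonneg = TRUE)
  if (poisson_ratio > 0.5)
    stop_domain("poisson_ratio must be in [0, 0.5] (got %g)", poisson_ratio)
  e_star <- youngs_modulus / (2 * (1 - poisson_ratio^2))
  a <- (3 * load * ball_radius / (4 * e_star))^(1 / 3)
  mean_p <- if (load == 0) 0 else load / (pi * a^2)
  structure(list(ball_radius = ball_radius, load = load,
                 youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio,
                 effective_modulus = e_star, contact_radius = a,
                 mean_pressure = mean_p, peak_pressure = 1.5 * mean_p),
            class = "sphere_contact")
}

#' @export
print.sphere_contact <- function(x, ...) {
  cat(sprintf(paste0("<sphere_contact> a = %.3g mm, mean p = %.3g kPa, ",
                     "peak p = %.3g kPa (E* = %.3g MPa)\n"),
              1e3 * x$contact_radius, 1e-3 * x$mean_pressure,
              1e-3 * x$peak_pressure, 1e-6 * x$effective_modulus))
  invisible(x)
}

#' Friction coefficient from measured torque (plate-on-plate)
#'
#' \eqn{\mu = M / (R F_N)}; vectorised over the torque.
#'
#' @param torque N.m, measured torque(s) \eqn{M}.
#' @param plate_radius m, plate radius \eqn{R} (default 0.025).
#' @param normal_force N, normal force \eqn{F_N} (default 1.0).
#' @return friction coefficient(s), dimensionless.
#' @export
friction_from_torque <- function(torque, plate_radius = 0.025,
                                 normal_force = 1.0) {
  check_number(plate_radius, "plate_radius", positive = TRUE)
  check_number(normal_force, "normal_force", positive = TRUE)
  if (any(!is.finite(torque))) stop_domain("torque must be finite")
  torque / (plate_radius * normal_force)
}

#' Entrainment speed from angular speed (plate-on-plate)
#'
#' \eqn{U = \Omega R}; the plate-on-plate sweep of 0.0050 to 1.2 1/s at
#' R = 0.025 m spans entrainment speeds 1.25e-4 to 0.03 m/s.
#'
#' @param angular_speed 1/s, angular speed(s) \eqn{\Omega}.
#' @param plate_radius m (default 0.025).
#' @return entrainment speed(s), m/s.
#' @export
entrainment_from_angular <- function(angular_speed, plate_radius = 0.025) {
  check_number(plate_radius, "plate_radius", positive = TRUE)
  if (any(!is.finite(angular_speed)) || any(angular_speed < 0))
    stop_domain("angular_speed must be finite and non-negative")
  angular_speed * plate_radius
}

#' Stribeck friction curve
#'
#' @param speed strictly increasing positive entrainment speeds, m/s.
#' @param mu non-negative friction coefficients.
#' @param surface `"smooth_pdms"` or `"biomimetic_tongue"`.
#' @param sliding_rolling_ratio percent, metadata (default 50).
#' @return An object of class `friction_curve`.
#' @export
friction_curve <- function(speed, mu,
                           surface = c("smooth_pdms", "biomimetic_tongue"),
                           sliding_rolling_ratio = 50) {
  surface <- match.arg(surface)
  if (length(speed) != length(mu) || length(speed) < 2L)
    stop_param("speed and mu must have equal length >= 2")
  if (any(!is.finite(speed)) || any(speed <= 0) || any(diff(speed) <= 0))
    stop_param("speeds must be finite, positive and strictly increasing")
  if (any(!is.finite(mu)) || any(mu < 0))
    stop_param("friction coefficients must be finite and >= 0")
  structure(list(speed = as.numeric(speed), mu = as.numeric(mu),
                 surface = surface,
                 sliding_rolling_ratio = sliding_rolling_ratio),
            class = "friction_curve")
}

#' @export
print.friction_curve <- function(x, ...) {
  cat(sprintf("<friction_curve> %d points, %.3g-%.3g m/s on %s\n",
              length(x$speed), min(x$speed), max(x$speed), x$surface))
  invisible(x)
}

#' Segment a Stribeck curve into lubrication regimes
#'
#' On the smoothed log-mu vs log-U curve (local quadratic, 5-point
#' window): the boundary plateau is the initial run of points whose
#' absolute log-log slope stays below `flatness`; the minimum of the
#' smoothed curve marks the end of the mixed regime; the hydrodynamic
#' regime starts at the first speed after the minimum where the slope
#' exceeds `+flatness`. The boundary friction coefficient is the median
#' of the measured mu over the plateau.
#'
#' @param curve a [friction_curve()] with at least 8 points spanning at
#'   least 1.5 decades of speed.
#' @param flatness log-log slope threshold (default 0.1).
#' @return An object of class `regime_segmentation` with elements
#'   `boundary_end`, `hydrodynamic_start` (m/s; NA when the rising
#'   branch is not reached), `boundary_mu`, `minimum_mu`,
#'   `minimum_speed`.
#' @export
segment_regimes <- function(curve, flatness = 0.1) {
  if (!inherits(curve, "friction_curve"))
    stop_param("curve must be a friction_curve")
  if (length(curve$speed) < 8L)
    stop_param("need >= 8 points to segment a Stribeck curve")
  if (log10(max(curve$speed) / min(curve$speed)) < 1.5)
    stop_param("speed range must span >= 1.5 decades")
  lu <- log(curve$speed); lm_ <- log(pmax(curve$mu, 1e-12))
  # degree-1 local fits: slope estimates stay low-variance in the one-sided
  # edge windows, where a quadratic term would be poorly determined
  sm <- local_poly_smooth(lu, lm_, span_frac = 0, min_pts = 5L, degree = 1L)
  slope <- sm$deriv
  flat0 <- abs(slope) < flatness
  if (!flat0[1L])
    sb_stop("salivabench_segmentation_error",
            "no boundary plateau: curve is not flat at the lowest speeds")
  n_flat <- match(FALSE, flat0, nomatch = length(flat0) + 1L) - 1L
  plateau <- seq_len(n_flat)
  # search for the friction minimum from the plateau end onward, so the
  # boundary_end <= minimum_speed <= hydrodynamic_start ordering holds even
  # when the curve rises monotonically out of the plateau
  i_min <- n_flat - 1L + which.min(sm$value[n_flat:length(sm$value)])
  after <- which(seq_along(slope) > i_min & slope > flatness)
  structure(list(boundary_end = curve$speed[n_flat],
                 hydrodynamic_start = if (length(after))
                   curve$speed[after[1L]] else NA_real_,
                 boundary_mu = stats::median(curve$mu[plateau]),
                 minimum_mu = exp(sm$value[i_min]),
                 minimum_speed = curve$speed[i_min]),
            class = "regime_segmentation")
}

#' @export
print.regime_segmentation <- function(x, ...) {
  cat(sprintf(paste0("<regime_segmentation> boundary mu = %.3g (plateau up ",
                     "to %.3g m/s), min mu = %.3g at %.3g m/s, hydrodynamic ",
                     "from %.3g m/s\n"),
              x$boundary_mu, x$boundary_end, x$minimum_mu, x$minimum_speed,
              x$hydrodynamic_start))
  invisible(x)
}

#' Friction coefficient at a reference speed
#'
#' Log-linear interpolation of mu versus log speed; refuses to
#' extrapolate outside the measured span.
#'
#' @param curve a [friction_curve()].
#' @param speed m/s.
#' @return friction coefficient, dimensionless.
#' @export
friction_at <- function(curve, speed) {
  if (!inherits(curve, "friction_curve"))
    stop_param("curve must be a friction_curve")
  check_number(speed, "speed", positive = TRUE)
  loglog_interp(curve$speed, curve$mu, speed, what = "speed")
}

#' Percent friction reduction relative to a reference
#'
#' \eqn{100 (1 - \mu_{sample} / \mu_{reference})}: positive when the
#' sample lubricates better than the reference.
#'
#' @param mu_sample friction coefficient of the sample (>= 0).
#' @param mu_reference friction coefficient of the reference (> 0).
#' @return percent reduction.
#' @export
percent_reduction <- function(mu_sample, mu_reference) {
  if (any(!is.finite(mu_reference)) || any(mu_reference <= 0))
    stop_domain("mu_reference must be positive")
  if (any(!is.finite(mu_sample)) || any(mu_sample < 0))
    stop_domain("mu_sample must be >= 0")
  100 * (1 - mu_sample / mu_reference)
}
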
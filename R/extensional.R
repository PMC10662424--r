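## Extensional rheology: CaBER filament-thinning analysis.
##
## Thinning models:
##   elastic (upper-convected Maxwell):  D(t) = D_start exp(-t / (3 lambda_c))
##   power law:                          D(t) = 2 phi0 (sigma/K) (t_b - t)^n,
##                                       phi0 = 0.142
## Derived pipeline: strain e = -2 ln(D/D_o); strain rate
## edot = -(2/D) dD/dt; apparent extensional viscosity
## eta_E = (2 sigma / D) / edot; Trouton ratio Tr = eta_E / eta_shear(edot)
## with the shear viscosity evaluated at a shear rate numerically equal to
## the instantaneous strain rate.

PHI0 <- 0.142

#' CaBER filament-thinning trace
#'
#' @param time strictly increasing times, s.
#' @param diameter minimum filament diameters, m, in (0, plate_diameter].
#' @param plate_diameter m, plate (and initial sample) diameter
#'   \eqn{D_0} (default 6e-3).
#' @param initial_separation m, initial plate gap \eqn{h_0}
#'   (default 3e-3).
#' @param final_separation m, final plate gap \eqn{h_f} (default 10e-3).
#' @param resolution m, laser-micrometer resolution floor (default 20e-6).
#' @return An object of class `thinning_trace`.
#' @export
thinning_trace <- function(time, diameter, plate_diameter = 6e-3,
                           initial_separation = 3e-3,
                           final_separation = 10e-3, resolution = 20e-6) {
  if (length(time) != length(diameter) || length(time) < 3L)
    stop_param("time and diameter must have equal length >= 3")
  if (any(!is.finite(time)) || any(diff(time) <= 0))
    stop_param("time must be finite and strictly increasing")
  check_number(plate_diameter, "plate_diameter", positive = TRUE)
  check_number(resolution, "resolution", positive = TRUE)
  if (any(!is.finite(diameter)) || any(diameter <= 0) ||
      any(diameter > plate_diameter * (1 + 1e-9)))
    stop_param("diameters must be finite, positive and <= plate_diameter")
  structure(list(time = as.numeric(time), diameter = as.numeric(diameter),
                 plate_diameter = plate_diameter,
                 initial_separation = initial_separation,
                 final_separation = final_separation,
                 resolution = resolution),
            class = "thinning_trace")
}

#' @export
print.thinning_trace <- function(x, ...) {
  cat(sprintf(paste0("<thinning_trace> %d points over %.3g s, D %.3g-%.3g ",
                     "mm (resolution %.3g um, aspect ratio %.2g)\n"),
              length(x$time), diff(range(x$time)), 1e3 * min(x$diameter),
              1e3 * max(x$diameter), 1e6 * x$resolution, aspect_ratio(x)))
  invisible(x)
}

#' Initial aspect ratio of the CaBER geometry
#'
#' \eqn{h_0 / D_0}: initial plate separation over plate diameter (0.5 for
#' the standard 3 mm / 6 mm configuration).
#'
#' @param trace a [thinning_trace()].
#' @return dimensionless aspect ratio.
#' @export
aspect_ratio <- function(trace) {
  trace$initial_separation / trace$plate_diameter
}

#' Hencky strain of a thinning filament
#'
#' \eqn{\varepsilon = -2 \ln(D_{min}/D_0)}; dimensionless, invariant to
#' the units the two diameters share. E.g. a filament at the 20 um
#' resolution floor between 6 mm plates has accumulated a strain of about
#' 11.41.
#'
#' @param diameter minimum filament diameter(s), m.
#' @param plate_diameter m, reference diameter \eqn{D_0} (default 6e-3).
#' @return strain(s), dimensionless.
#' @export
hencky_strain <- function(diameter, plate_diameter = 6e-3) {
  -2 * log(diameter / plate_diameter)
}

#' Detect the filament breakup time
#'
#' The breakup time is the earliest time at which the diameter reaches the
#' resolution floor and never rises above it again: a single noise spike
#' that dips below the floor and recovers is ignored.
#'
#' @param trace a [thinning_trace()].
#' @return breakup time in s, or `NA_real_` if the filament never breaks
#'   within the trace.
#' @export
detect_breakup <- function(trace) {
  if (!inherits(trace, "thinning_trace"))
    stop_param("trace must be a thinning_trace")
  above <- which(trace$diameter > trace$resolution)
  if (!length(above)) return(trace$time[1L])
  last_above <- above[length(above)]
  if (last_above == length(trace$time)) return(NA_real_)
  trace$time[last_above + 1L]
}

# Usable-point bookkeeping shared by the fitting routines: drop the initial
# plateau (longest initial run with D > 95% of the starting diameter), all
# censored points at the resolution floor, and beads-on-a-string artifacts
# (local diameter increases > 5% between neighbours).
usable_points <- function(trace, plateau_frac = 0.95, beads_tol = 0.05) {
  d <- trace$diameter
  n <- length(d)
  keep <- rep(TRUE, n)
  ip <- initial_plateau_end(d, plateau_frac)
  if (ip > 0L) keep[seq_len(ip)] <- FALSE
  keep[d <= trace$resolution * (1 + 1e-12)] <- FALSE
  keep[beads_mask(d, beads_tol)] <- FALSE
  keep
}

contiguous_runs <- function(keep) {
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  Map(function(s, e) s:e, starts[r$values], ends[r$values])
}

#' Fit the elastocapillary (elastic) thinning model
#'
#' Linear regression of \eqn{\ln D} on \eqn{t} over an automatically
#' selected window: after discarding the initial plateau, censored points
#' and beads-on-a-string artifacts, the longest contiguous window whose
#' log-linear fit has an rms residual below `rms_threshold` is used
#' (trimmed from the noisier end if necessary). The relaxation time is
#' \eqn{\lambda_c = -1/(3 \times \mathrm{slope})}.
#'
#' @param trace a [thinning_trace()] with at least 8 usable points.
#' @param rms_threshold maximum acceptable rms log-residual of the fitted
#'   window (default 0.05).
#' @return An object of class `elastic_fit` with elements `lambda_c`,
#'   `window` (fitted time span), `rms_log_residual`.
#' @export
fit_elastic <- function(trace, rms_threshold = 0.05) {
  if (!inherits(trace, "thinning_trace"))
    stop_param("trace must be a thinning_trace")
  keep <- usable_points(trace)
  runs <- contiguous_runs(keep)
  runs <- runs[vapply(runs, length, integer(1L)) >= 8L]
  if (!length(runs))
    stop_fit("fewer than 8 usable points above the resolution floor")
  best <- NULL
  for (idx in runs) {
    # trim 10% from the worse-fitting end until the window is acceptable
    while (length(idx) >= 8L) {
      f <- lm(log(trace$diameter[idx]) ~ trace$time[idx])
      r <- stats::resid(f)
      if (rms(r) < rms_threshold) break
      k <- max(1L, round(0.1 * length(idx)))
      head_bad <- mean(abs(r[seq_len(k)]))
      tail_bad <- mean(abs(r[seq(length(r) - k + 1L, length(r))]))
      idx <- if (head_bad > tail_bad) idx[-seq_len(k)]
             else idx[-seq(length(idx) - k + 1L, length(idx))]
    }
    if (length(idx) < 8L) next
    f <- lm(log(trace$diameter[idx]) ~ trace$time[idx])
    if (rms(stats::resid(f)) >= rms_threshold) next
    if (is.null(best) || length(idx) > length(best$idx))
      best <- list(idx = idx, fit = f)
  }
  if (is.null(best))
    stop_fit("no contiguous window fits an exponential decay (rms < %g)",
             rms_threshold)
  slope <- coef(best$fit)[[2L]]
  if (slope >= 0) stop_fit("no exponential decay detected (slope >= 0)")
  structure(list(lambda_c = -1 / (3 * slope),
                 window = range(trace$time[best$idx]),
                 n_points = length(best$idx),
                 rms_log_residual = rms(stats::resid(best$fit))),
            class = "elastic_fit")
}

#' @export
print.elastic_fit <- function(x, ...) {
  cat(sprintf(paste0("<elastic_fit> lambda_c = %.4g s over [%.3g, %.3g] s ",
                     "(%d points, rms log resid %.3g)\n"),
              x$lambda_c, x$window[1L], x$window[2L], x$n_points,
              x$rms_log_residual))
  invisible(x)
}

#' Fit the power-law thinning model
#'
#' Nonlinear least squares on \eqn{\ln D} for
#' \eqn{D(t) = 2\phi_0(\sigma/K)(t_b - t)^n} over \eqn{(K, n, t_b)}, with
#' \eqn{\phi_0} fixed at 0.142. The breakup time is initialised from
#' [detect_breakup()] (or the last sample plus one interval when no
#' breakup is observed) and constrained to lie beyond the last usable
#' sample; \eqn{(K, n)} are initialised by linear regression of
#' \eqn{\ln D} on \eqn{\ln(t_b - t)} at the initial \eqn{t_b}.
#'
#' @param trace a [thinning_trace()] with at least 8 usable points.
#' @param sigma N/m, surface tension of the sample.
#' @return An object of class `power_law_fit` with elements `K`, `n`,
#'   `t_b`, `phi0`, `sigma`, `rms_log_residual`.
#' @export
fit_power_law <- function(trace, sigma) {
  if (!inherits(trace, "thinning_trace"))
    stop_param("trace must be a thinning_trace")
  check_number(sigma, "sigma", positive = TRUE)
  keep <- usable_points(trace)
  idx <- which(keep)
  if (length(idx) < 8L)
    stop_fit("fewer than 8 usable points above the resolution floor")
  t <- trace$time[idx]; d <- trace$diameter[idx]
  dt <- stats::median(diff(trace$time))
  tb0 <- detect_breakup(trace)
  t_last <- max(t)
  if (is.na(tb0) || tb0 <= t_last) tb0 <- t_last + dt
  # linear init for (K, n) given tb0: ln D = ln(2 phi0 sigma / K) + n ln(tb0 - t)
  init <- lm(log(d) ~ log(tb0 - t))
  n0 <- max(0.05, min(1.5, coef(init)[[2L]]))
  K0 <- 2 * PHI0 * sigma / exp(coef(init)[[1L]])
  df <- data.frame(t = t, ld = log(d))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ld ~ log(2 * PHI0 * sigma / exp(lK)) + n * log(tb - t),
      data = df, start = list(lK = log(K0), n = n0, tb = tb0),
      lower = c(-50, 1e-3, t_last + 1e-9 + dt / 1e6),
      upper = c(50, 1.5, t_last + 1e4 * dt),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop_fit("power-law fit did not converge: %s", conditionMessage(e)))
  cf <- coef(fit)
  if (cf[["tb"]] <= t_last)
    stop_fit("inconsistent breakup time: fitted t_b %.4g s precedes the last usable sample %.4g s",
             cf[["tb"]], t_last)
  structure(list(K = exp(cf[["lK"]]),
                 n = cf[["n"]], t_b = cf[["tb"]], phi0 = PHI0, sigma = sigma,
                 window = range(t), n_points = length(idx),
                 rms_log_residual = rms(stats::resid(fit))),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(paste0("<power_law_fit> K = %.4g Pa.s^n, n = %.3f, t_b = ",
                     "%.4g s (sigma = %.3g N/m, rms log resid %.3g)\n"),
              x$K, x$n, x$t_b, x$sigma, x$rms_log_residual))
  invisible(x)
}

#' Predict the filament diameter from a thinning fit
#'
#' @param object an `elastic_fit` or `power_law_fit`.
#' @param time times, s.
#' @param D_start m, diameter at the start of the fitted window (elastic
#'   model only; the elastocapillary law fixes only the decay rate).
#' @param ... unused.
#' @return diameters, m (0 beyond breakup for the power-law model).
#' @export
predict.power_law_fit <- function(object, time, ...) {
  with(object, 2 * phi0 * (sigma / K) * pmax(t_b - time, 0)^n)
}

#' @rdname predict.power_law_fit
#' @export
predict.elastic_fit <- function(object, time, D_start = 1, ...) {
  D_start * exp(-(time - object$window[1L]) / (3 * object$lambda_c))
}

#' Select the better thinning model for a trace
#'
#' Attempts both the elastic and the power-law fit and selects the one
#' with the lower rms log-residual (ties go to the power law, the model
#' describing most saliva substitutes); a model that fails to converge is
#' simply not selected.
#'
#' @param trace a [thinning_trace()].
#' @param sigma N/m, surface tension.
#' @return A list with `choice` (`"elastic"` or `"power_law"`),
#'   `elastic` (an `elastic_fit` or NULL) and `power_law`
#'   (a `power_law_fit` or NULL).
#' @export
select_thinning_model <- function(trace, sigma) {
  ef <- tryCatch(fit_elastic(trace), salivabench_error = function(e) NULL)
  pf <- tryCatch(fit_power_law(trace, sigma),
                 salivabench_error = function(e) NULL)
  if (is.null(ef) && is.null(pf))
    stop_analysis("neither thinning model could be fitted to this trace")
  choice <- if (is.null(pf)) "elastic"
            else if (is.null(ef)) "power_law"
            else if (ef$rms_log_residual < pf$rms_log_residual) "elastic"
            else "power_law"
  list(choice = choice, elastic = ef, power_law = pf)
}

#' Strain, strain rate, extensional viscosity and Trouton ratio
#'
#' Computes, for the thinning segment of a CaBER trace, the Hencky strain
#' \eqn{\varepsilon = -2\ln(D/D_0)} (with \eqn{D_0} the plate diameter),
#' the instantaneous strain rate
#' \eqn{\dot\varepsilon = -(2/D)\,dD/dt} via local-quadratic smoothed
#' numerical differentiation, the apparent extensional viscosity
#' \eqn{\eta_E = (2\sigma/D)/\dot\varepsilon}, and the Trouton ratio
#' \eqn{T_r = \eta_E / \eta_{shear}(\dot\varepsilon)} with the shear
#' viscosity taken from a fitted Cross model at a shear rate numerically
#' equal to the strain rate (no sqrt(3) kinematic conversion).
#'
#' Smoothing and differentiation are confined to the post-plateau,
#' above-resolution thinning segment so that windows never straddle the
#' plateau kink or the censored floor; beads-on-a-string artifacts are
#' masked from the local fits. Maxima of \eqn{\eta_E} and \eqn{T_r} are
#' extracted independently over the valid window: diameters below 95% of
#' the post-plateau start value and above the resolution floor, strain
#' rates above `rate_floor`.
#'
#' @param trace a [thinning_trace()].
#' @param sigma N/m, surface tension.
#' @param shear_fit a [fit_shear_model()] result (needed for the Trouton
#'   ratio; may be NULL, in which case `trouton` is NA).
#' @param span_frac fraction of the segment length used as the smoothing
#'   window (default 0.05, minimum 5 points).
#' @param rate_floor 1/s, minimum strain rate entering the maxima (default
#'   1e-3); the extensional viscosity is singular as the strain rate
#'   vanishes.
#' @return An object of class `extensional_profile`: a list with a
#'   data.frame `profile` (`time`, `diameter`, `strain`, `strain_rate`,
#'   `eta_extensional`, `trouton`, `valid`) and scalars
#'   `max_eta_extensional`, `max_trouton`.
#' @export
extensional_profile <- function(trace, sigma, shear_fit = NULL,
                                span_frac = 0.05, rate_floor = 1e-3) {
  if (!inherits(trace, "thinning_trace"))
    stop_param("trace must be a thinning_trace")
  check_number(sigma, "sigma", positive = TRUE)
  if (!is.null(shear_fit) && !inherits(shear_fit, "shear_model_fit"))
    stop_param("shear_fit must be a shear_model_fit (or NULL)")
  d_all <- trace$diameter
  ip <- initial_plateau_end(d_all, 0.95)
  floor_pts <- d_all <= trace$resolution * (1 + 1e-12)
  seg <- which(!floor_pts & seq_along(d_all) > ip)
  if (length(seg) >= 1L)
    seg <- seg[seq_len(match(TRUE, diff(seg) > 1L, nomatch = length(seg)))]
  if (length(seg) < 5L)
    stop_analysis("no valid thinning region between the plateau and the resolution floor")
  t <- trace$time[seg]; d <- d_all[seg]
  mask <- !beads_mask(d, 0.05)
  sm <- local_poly_smooth(t, d, span_frac = span_frac, min_pts = 5L,
                          degree = 2L, mask = mask)
  dsm <- sm$value
  dsm[!is.finite(dsm) | dsm <= 0] <- NA_real_
  strain <- hencky_strain(dsm, trace$plate_diameter)
  rate <- -2 * sm$deriv / dsm
  eta_e <- (2 * sigma / dsm) / rate
  trouton <- if (is.null(shear_fit)) rep(NA_real_, length(rate))
             else eta_e / predict(shear_fit, rate)
  d_start <- d[1L]
  valid <- is.finite(rate) & rate > rate_floor &
    dsm < 0.95 * d_start & dsm > trace$resolution
  if (!any(valid))
    stop_analysis("no valid thinning region (all strain rates below the floor)")
  prof <- data.frame(time = t, diameter = d, strain = strain,
                     strain_rate = rate, eta_extensional = eta_e,
                     trouton = trouton, valid = valid)
  structure(list(profile = prof,
                 max_eta_extensional = max(eta_e[valid], na.rm = TRUE),
                 max_trouton = if (all(is.na(trouton[valid]))) NA_real_
                               else max(trouton[valid], na.rm = TRUE),
                 sigma = sigma, rate_floor = rate_floor),
            class = "extensional_profile")
}

#' @export
print.extensional_profile <- function(x, ...) {
  cat(sprintf(paste0("<extensional_profile> %d points (%d valid), max ",
                     "eta_E = %.4g Pa.s, max Tr = %.4g\n"),
              nrow(x$profile), sum(x$profile$valid),
              x$max_eta_extensional, x$max_trouton))
  invisible(x)
}
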
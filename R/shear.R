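## Shear rheology: flow curves, Cross-model fitting, apparent viscosity at
## the orally relevant shear rate (50 1/s) and format classification.

#' Flow curve (shear rate vs apparent viscosity)
#'
#' @param shear_rate strictly increasing positive shear rates, 1/s.
#' @param viscosity positive apparent viscosities, Pa.s.
#' @param replicate_id replicate label.
#' @param temperature degrees C, metadata (default 37, oral temperature).
#' @return An object of class `flow_curve`.
#' @export
flow_curve <- function(shear_rate, viscosity, replicate_id = "r1",
                       temperature = 37) {
  if (length(shear_rate) != length(viscosity) || length(shear_rate) < 3L)
    stop_param("shear_rate and viscosity must have equal length >= 3")
  if (any(!is.finite(shear_rate)) || any(shear_rate <= 0) ||
      any(diff(shear_rate) <= 0))
    stop_param("shear rates must be finite, positive and strictly increasing")
  if (any(!is.finite(viscosity)) || any(viscosity <= 0))
    stop_param("viscosities must be finite and positive")
  structure(list(shear_rate = as.numeric(shear_rate),
                 viscosity = as.numeric(viscosity),
                 replicate_id = replicate_id,
                 temperature = temperature),
            class = "flow_curve")
}

#' @export
print.flow_curve <- function(x, ...) {
  cat(sprintf("<flow_curve> %d points, %.3g-%.3g 1/s, replicate %s, %g C\n",
              length(x$shear_rate), min(x$shear_rate), max(x$shear_rate),
              x$replicate_id, x$temperature))
  invisible(x)
}

#' Apparent viscosity at a given shear rate
#'
#' Log-log linear interpolation between the bracketing measured points;
#' exact node values are returned at the nodes and queries outside the
#' measured range raise an extrapolation error.
#'
#' @param curve a [flow_curve()].
#' @param rate shear rate, 1/s (default 50, the orally relevant rate).
#' @return apparent viscosity in Pa.s.
#' @export
viscosity_at <- function(curve, rate = 50) {
  if (!inherits(curve, "flow_curve")) stop_param("curve must be a flow_curve")
  check_number(rate, "rate", positive = TRUE)
  loglog_interp(curve$shear_rate, curve$viscosity, rate, what = "shear rate")
}

#' Fit a Cross shear-thinning model to a flow curve
#'
#' Least squares on log-viscosity,
#' \deqn{\eta(\dot\gamma) = \eta_\infty + (\eta_0 - \eta_\infty) /
#'   (1 + (\lambda\dot\gamma)^m),}
#' with the deterministic initialisation \eqn{\eta_0 = \max\eta},
#' \eqn{\eta_\infty = \min\eta}, \eqn{\lambda} = reciprocal of the rate at
#' the geometric-mean viscosity, \eqn{m = 1}. The fitted model supplies the
#' rate-dependent shear viscosity needed in the denominator of the
#' strain-rate-matched Trouton ratio.
#'
#' @param curve a [flow_curve()] with at least 5 points.
#' @return An object of class `shear_model_fit` with elements `eta_zero`,
#'   `eta_inf`, `cross_time`, `cross_exponent`, `rms_log_residual`.
#' @export
fit_shear_model <- function(curve) {
  if (!inherits(curve, "flow_curve")) stop_param("curve must be a flow_curve")
  g <- curve$shear_rate; eta <- curve$viscosity
  if (length(g) < 5L) stop_param("need >= 5 points to fit the Cross model")
  if (max(eta) / min(eta) - 1 < 1e-8) {
    # Newtonian: both plateaus equal the constant, cross_time immaterial
    fit <- list(eta_zero = mean(eta), eta_inf = mean(eta), cross_time = 1,
                cross_exponent = 1,
                rms_log_residual = rms(log(eta) - log(mean(eta))))
    return(structure(fit, class = "shear_model_fit"))
  }
  eta_gm <- exp(mean(range(log(eta))))
  rate_gm <- exp(stats::approx(log(eta), log(g), xout = log(eta_gm),
                               ties = "ordered")$y)
  if (!is.finite(rate_gm)) rate_gm <- exp(mean(range(log(g))))
  start <- list(l_eta0 = log(max(eta)), l_etainf = log(min(eta)),
                l_lambda = log(1 / rate_gm), m = 1)
  df <- data.frame(g = g, leta = log(eta))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      leta ~ log(exp(l_etainf) + (exp(l_eta0) - exp(l_etainf)) /
                   (1 + (exp(l_lambda) * g)^m)),
      data = df, start = start,
      lower = c(-50, -50, -50, 1e-3), upper = c(50, 50, 50, 5),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop_fit("Cross-model fit did not converge: %s", conditionMessage(e)))
  cf <- coef(fit)
  out <- list(eta_zero = exp(cf[["l_eta0"]]), eta_inf = exp(cf[["l_etainf"]]),
              cross_time = exp(cf[["l_lambda"]]),
              cross_exponent = cf[["m"]],
              rms_log_residual = rms(stats::resid(fit)))
  if (out$eta_zero < out$eta_inf)
    stop_fit("fitted eta_zero < eta_inf: curve is not shear-thinning")
  structure(out, class = "shear_model_fit")
}

#' @export
print.shear_model_fit <- function(x, ...) {
  cat(sprintf(paste0("<shear_model_fit> eta0 = %.4g Pa.s, eta_inf = %.4g ",
                     "Pa.s, lambda = %.4g s, m = %.3f (rms log resid %.3g)\n"),
              x$eta_zero, x$eta_inf, x$cross_time, x$cross_exponent,
              x$rms_log_residual))
  invisible(x)
}

#' Predict shear viscosity from a fitted Cross model
#'
#' @param object a `shear_model_fit`.
#' @param rate shear rate(s), 1/s.
#' @param ... unused.
#' @return apparent viscosity, Pa.s.
#' @export
predict.shear_model_fit <- function(object, rate, ...) {
  object$eta_inf + (object$eta_zero - object$eta_inf) /
    (1 + (object$cross_time * rate)^object$cross_exponent)
}

#' Classify a sample by its apparent viscosity at 50 1/s
#'
#' Format categories: `liquid` for \eqn{\eta < 0.10} Pa.s,
#' `viscous_liquid` for \eqn{0.10 \le \eta \le 1.0} Pa.s (closed
#' interval), `gel` for \eqn{\eta > 1.0} Pa.s.
#'
#' @param eta_at_reference apparent viscosity at the reference rate, Pa.s.
#' @param reference_rate 1/s, metadata (default 50).
#' @return An object of class `viscosity_class` with elements `label`,
#'   `eta_at_reference`, `reference_rate`.
#' @export
classify_viscosity <- function(eta_at_reference, reference_rate = 50) {
  check_number(eta_at_reference, "eta_at_reference")
  if (eta_at_reference <= 0)
    stop_domain("viscosity must be positive (got %g)", eta_at_reference)
  label <- if (eta_at_reference < 0.10) "liquid"
           else if (eta_at_reference <= 1.0) "viscous_liquid"
           else "gel"
  structure(list(label = label, eta_at_reference = eta_at_reference,
                 reference_rate = reference_rate),
            class = "viscosity_class")
}

#' @export
print.viscosity_class <- function(x, ...) {
  cat(sprintf("<viscosity_class> %s (eta = %.4g Pa.s at %g 1/s)\n",
              x$label, x$eta_at_reference, x$reference_rate))
  invisible(x)
}

#' Average replicate flow curves
#'
#' Pointwise mean and sample standard deviation over replicates measured
#' on identical shear-rate grids.
#'
#' @param curves a list of at least two [flow_curve()] objects.
#' @return A list with `mean` (a [flow_curve()] of the pointwise means)
#'   and `sd` (pointwise sample standard deviations).
#' @export
aggregate_replicates <- function(curves) {
  if (!is.list(curves) || length(curves) < 2L ||
      !all(vapply(curves, inherits, logical(1L), "flow_curve")))
    sb_stop("salivabench_alignment_error",
            "need a list of >= 2 flow_curve objects to aggregate")
  grid <- curves[[1L]]$shear_rate
  same <- vapply(curves, function(cv)
    length(cv$shear_rate) == length(grid) &&
      all(cv$shear_rate == grid), logical(1L))
  if (!all(same))
    sb_stop("salivabench_alignment_error",
            "replicate shear-rate grids differ; cannot aggregate")
  eta <- vapply(curves, `[[`, numeric(length(grid)), "viscosity")
  list(mean = flow_curve(grid, rowMeans(eta), replicate_id = "mean",
                         temperature = curves[[1L]]$temperature),
       sd = apply(eta, 1L, sd))
}
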
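## Synthetic instrument-trace generators. Every generator takes an explicit
## seed and leaves the caller's RNG state untouched; identical (params, seed)
## give bit-identical output.

#' Evaluate the Cross-type shear-thinning law
#'
#' @param params a [flow_curve_params()] object.
#' @param rate shear rate(s), 1/s.
#' @return apparent viscosity, Pa.s.
#' @export
cross_viscosity <- function(params, rate) {
  with(params, infinite_shear_viscosity +
         (zero_shear_viscosity - infinite_shear_viscosity) /
         (1 + (relaxation_time * rate)^thinning_exponent))
}

#' Generate synthetic flow-curve replicates
#'
#' Log-spaced shear rates over `params$rate_range`; viscosity follows the
#' Cross law [cross_viscosity()] times independent multiplicative lognormal
#' noise with the declared CV. Replicates differ only by noise.
#'
#' @param params a [flow_curve_params()] object.
#' @param seed integer seed.
#' @return A list of [flow_curve()] objects, one per replicate.
#' @export
generate_flow_curve <- function(params, seed) {
  if (!inherits(params, "flow_curve_params"))
    stop_param("params must be a flow_curve_params object")
  rate <- geomspace(params$rate_range[1L], params$rate_range[2L],
                    params$n_points)
  eta <- cross_viscosity(params, rate)
  withr::with_seed(seed, {
    lapply(seq_len(params$n_replicates), function(r)
      flow_curve(rate, eta * lognormal_noise(length(eta), params$noise_cv),
                 replicate_id = sprintf("r%d", r)))
  })
}

# Noiseless diameter law shared by the generator and its tests.
thinning_law <- function(params, t) {
  d <- rep(params$D0, length(t))
  post <- t > params$initial_plateau
  if (params$model == "elastic") {
    d[post] <- params$D0 *
      exp(-(t[post] - params$initial_plateau) / (3 * params$lambda_c))
  } else {
    tt <- pmin(t[post], params$t_b)
    d[post] <- 2 * params$phi0 * (params$sigma / params$K) *
      (params$t_b - tt)^params$n
  }
  d
}

#' Generate a synthetic CaBER filament-thinning trace
#'
#' Diameter equals `D0` during the initial plateau, then follows the
#' declared thinning model (elastocapillary exponential decay, or power law
#' with prefactor 0.142) times multiplicative lognormal noise. Values at or
#' below the laser resolution are censored to the resolution floor, as a
#' laser micrometer reports them.
#'
#' @param params a [thinning_params()] object.
#' @param seed integer seed.
#' @return A [thinning_trace()] object.
#' @export
generate_thinning_trace <- function(params, seed) {
  if (!inherits(params, "thinning_params"))
    stop_param("params must be a thinning_params object")
  t <- seq(0, params$duration, by = 1 / params$sampling_rate)
  d <- thinning_law(params, t)
  d <- withr::with_seed(seed,
                        d * lognormal_noise(length(d), params$noise_cv))
  d <- pmin(d, params$D0)
  d[d <= params$resolution] <- params$resolution
  if (params$model == "power_law") d[t >= params$t_b] <- params$resolution
  thinning_trace(t, d, resolution = params$resolution)
}

# Noiseless Stribeck law shared by the generator and its tests.
stribeck_law <- function(params, speed) {
  w <- 1 / (1 + (speed / params$transition_speed)^params$transition_sharpness)
  hydro <- params$hydrodynamic_coeff *
    (params$viscosity_at_contact * speed)^params$hydrodynamic_exponent
  w * params$boundary_mu + (1 - w) * hydro
}

#' Generate a synthetic Stribeck curve
#'
#' Friction coefficient versus entrainment speed with a boundary plateau, a
#' logistic mixed-regime transition in log-speed, and a rising hydrodynamic
#' branch \eqn{c (\eta U)^p}, times multiplicative lognormal noise.
#'
#' @param params a [stribeck_params()] object.
#' @param seed integer seed.
#' @param surface surface label stored on the curve.
#' @return A [friction_curve()] object.
#' @export
generate_friction_curve <- function(params, seed, surface = "smooth_pdms") {
  if (!inherits(params, "stribeck_params"))
    stop_param("params must be a stribeck_params object")
  speed <- geomspace(params$speed_range[1L], params$speed_range[2L],
                     params$n_points)
  mu <- stribeck_law(params, speed)
  mu <- withr::with_seed(seed,
                         mu * lognormal_noise(length(mu), params$noise_cv))
  friction_curve(speed, mu, surface = surface)
}

# Noiseless frequency-shift law shared by the generator and its tests.
qcmd_law <- function(params, t) {
  f <- numeric(length(t))
  ads <- t >= params$injection_time & t < params$rinse_time
  f[ads] <- -params$plateau_shift *
    (1 - exp(-(t[ads] - params$injection_time) / params$adsorption_tau))
  post <- t >= params$rinse_time
  f_rinse <- -params$plateau_shift *
    (1 - exp(-(params$rinse_time - params$injection_time) /
               params$adsorption_tau))
  target <- -params$plateau_shift * (1 - params$removal_fraction)
  f[post] <- target + (f_rinse - target) *
    exp(-(t[post] - params$rinse_time) / params$desorption_tau)
  f
}

#' Generate a synthetic QCM-D frequency trace
#'
#' Flat (noisy) baseline before injection; exponential adsorption transient
#' towards \eqn{-|\Delta f|_{plateau}}; after the rinse, exponential
#' relaxation towards \eqn{-|\Delta f|_{plateau}(1 - r)}. Noise is additive
#' Gaussian (counter noise).
#'
#' @param params a [qcmd_params()] object.
#' @param seed integer seed.
#' @return A [qcmd_trace()] object.
#' @export
generate_qcmd_trace <- function(params, seed) {
  if (!inherits(params, "qcmd_params"))
    stop_param("params must be a qcmd_params object")
  t <- seq(0, params$duration, by = params$sampling_interval)
  f <- qcmd_law(params, t)
  f <- withr::with_seed(seed,
                        f + stats::rnorm(length(f),
                                         sd = params$baseline_noise_sd))
  qcmd_trace(t, f, injection_time = params$injection_time,
             rinse_time = params$rinse_time)
}

#' Generate the full synthetic data set for one preset
#'
#' Convenience wrapper: generates flow-curve replicates, a thinning trace,
#' a Stribeck curve and a QCM-D trace for one preset class, with
#' sub-seeds derived deterministically from `seed`.
#'
#' @param name preset name, see [preset_params()].
#' @param seed integer seed.
#' @return A list with elements `preset`, `params`, `flow` (list of
#'   replicates), `thinning`, `friction`, `qcmd`, `sigma`.
#' @export
generate_preset_sample <- function(name, seed) {
  p <- preset_params(name)
  list(preset = name, params = p,
       flow = generate_flow_curve(p$flow, seed),
       thinning = generate_thinning_trace(p$thinning, seed + 1L),
       friction = generate_friction_curve(p$stribeck, seed + 2L),
       qcmd = generate_qcmd_trace(p$qcmd, seed + 3L),
       sigma = p$sigma)
}
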
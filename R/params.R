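## Ground-truth parameter sets for the synthetic instrument generators.
## All quantities are SI internally (Pa.s, s, m, N/m, Hz).

#' Parameters for a synthetic shear-thinning flow curve
#'
#' The generating law is a four-parameter Cross-type model
#' \deqn{\eta(\dot\gamma) = \eta_\infty + (\eta_0 - \eta_\infty) /
#'   (1 + (\lambda\dot\gamma)^m),}
#' which reproduces in one family both near-Newtonian liquids with a
#' low-rate plateau and strongly shear-thinning gels spanning three decades
#' of viscosity.
#'
#' @param zero_shear_viscosity Pa.s, low-rate plateau \eqn{\eta_0}.
#' @param infinite_shear_viscosity Pa.s, high-rate plateau
#'   \eqn{\eta_\infty}.
#' @param relaxation_time s, Cross time constant \eqn{\lambda} (reciprocal
#'   of the rate where thinning sets in).
#' @param thinning_exponent dimensionless Cross exponent \eqn{m}.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   measurement noise (default 0.02).
#' @param n_points samples per replicate, log-spaced over `rate_range`.
#' @param rate_range length-2 numeric, shear-rate window in 1/s (default
#'   0.1 to 1000, the instrument sweep).
#' @param n_replicates number of replicate curves (default 3).
#' @return An object of class `flow_curve_params`.
#' @export
flow_curve_params <- function(zero_shear_viscosity,
                              infinite_shear_viscosity,
                              relaxation_time,
                              thinning_exponent,
                              noise_cv = 0.02,
                              n_points = 40L,
                              rate_range = c(0.1, 1000),
                              n_replicates = 3L) {
  check_number(zero_shear_viscosity, "zero_shear_viscosity", positive = TRUE)
  check_number(infinite_shear_viscosity, "infinite_shear_viscosity",
               positive = TRUE)
  if (zero_shear_viscosity < infinite_shear_viscosity)
    stop_param("zero_shear_viscosity (%g) must be >= infinite_shear_viscosity (%g)",
               zero_shear_viscosity, infinite_shear_viscosity)
  check_number(relaxation_time, "relaxation_time", positive = TRUE)
  check_number(thinning_exponent, "thinning_exponent", positive = TRUE)
  check_number(noise_cv, "noise_cv", nonneg = TRUE)
  if (length(rate_range) != 2L || any(rate_range <= 0) ||
      diff(rate_range) <= 0)
    stop_param("rate_range must be strictly positive and increasing")
  if (n_points < 3L) stop_param("n_points must be >= 3")
  if (n_replicates < 1L) stop_param("n_replicates must be >= 1")
  structure(list(zero_shear_viscosity = zero_shear_viscosity,
                 infinite_shear_viscosity = infinite_shear_viscosity,
                 relaxation_time = relaxation_time,
                 thinning_exponent = thinning_exponent,
                 noise_cv = noise_cv,
                 n_points = as.integer(n_points),
                 rate_range = as.numeric(rate_range),
                 n_replicates = as.integer(n_replicates)),
            class = "flow_curve_params")
}

#' Parameters for a synthetic CaBER filament-thinning trace
#'
#' Two generating models are supported, matching the two regimes seen in
#' capillary-breakup rheometry of saliva substitutes:
#' \describe{
#'   \item{elastic}{elastocapillary thinning of an upper-convected Maxwell
#'     fluid, \eqn{D(t) = D_0 e^{-(t - t_0)/(3\lambda_c)}} after an initial
#'     plateau ending at \eqn{t_0};}
#'   \item{power_law}{\eqn{D(t) = 2\phi_0 (\sigma/K)(t_b - t)^n} with
#'     prefactor \eqn{\phi_0 = 0.142}, breakup time \eqn{t_b} and surface
#'     tension \eqn{\sigma}.}
#' }
#' Diameters below the laser-micrometer resolution are censored at the
#' resolution floor, as the instrument reports them.
#'
#' @param model `"elastic"` or `"power_law"`.
#' @param lambda_c s, relaxation time (elastic model only).
#' @param K Pa.s^n, power-law consistency (power-law model only).
#' @param n dimensionless power-law exponent in (0, 1.5].
#' @param t_b s, filament breakup time (power-law model only).
#' @param sigma N/m, surface tension.
#' @param D0 m, initial filament diameter (default 6e-3, the plate
#'   diameter).
#' @param initial_plateau s, duration of the initial constant-diameter
#'   regime.
#' @param resolution m, laser-micrometer resolution floor (default 20e-6).
#' @param sampling_rate Hz.
#' @param noise_cv multiplicative noise CV (default 0.02).
#' @param duration s, trace length; defaults to slightly past breakup.
#' @return An object of class `thinning_params`.
#' @export
thinning_params <- function(model = c("elastic", "power_law"),
                            lambda_c = NULL, K = NULL, n = NULL, t_b = NULL,
                            sigma, D0 = 6e-3, initial_plateau = 0.05,
                            resolution = 20e-6, sampling_rate = 1000,
                            noise_cv = 0.02, duration = NULL) {
  model <- match.arg(model)
  check_number(sigma, "sigma", positive = TRUE)
  check_number(D0, "D0", positive = TRUE)
  check_number(initial_plateau, "initial_plateau", nonneg = TRUE)
  check_number(resolution, "resolution", positive = TRUE)
  check_number(sampling_rate, "sampling_rate", positive = TRUE)
  check_number(noise_cv, "noise_cv", nonneg = TRUE)
  phi0 <- 0.142
  if (model == "elastic") {
    if (is.null(lambda_c) || !is.null(K) || !is.null(n) || !is.null(t_b))
      stop_param("elastic model takes exactly {lambda_c}; K, n, t_b must be unset")
    check_number(lambda_c, "lambda_c", positive = TRUE)
    if (is.null(duration))
      duration <- initial_plateau + 3 * lambda_c * log(D0 / resolution) * 1.05
  } else {
    if (is.null(K) || is.null(n) || is.null(t_b) || !is.null(lambda_c))
      stop_param("power_law model takes exactly {K, n, t_b}; lambda_c must be unset")
    check_number(K, "K", positive = TRUE)
    check_number(n, "n", positive = TRUE)
    if (n > 1.5) stop_param("power-law exponent n must be in (0, 1.5]")
    check_number(t_b, "t_b", positive = TRUE)
    if (t_b <= initial_plateau)
      stop_param("t_b (%g s) must exceed initial_plateau (%g s)",
                 t_b, initial_plateau)
    d_start <- 2 * phi0 * (sigma / K) * (t_b - initial_plateau)^n
    if (d_start > D0)
      stop_param(paste0("power-law model evaluates to %.3g m at the end of ",
                        "the initial plateau, exceeding the plate diameter ",
                        "D0 = %.3g m"), d_start, D0)
    if (is.null(duration)) duration <- t_b * 1.05
  }
  check_number(duration, "duration", positive = TRUE)
  structure(list(model = model, lambda_c = lambda_c, K = K, n = n, t_b = t_b,
                 phi0 = phi0, sigma = sigma, D0 = D0,
                 initial_plateau = initial_plateau, resolution = resolution,
                 sampling_rate = sampling_rate, noise_cv = noise_cv,
                 duration = duration),
            class = "thinning_params")
}

#' Parameters for a synthetic Stribeck (friction) curve
#'
#' The generating law blends a boundary plateau with a rising hydrodynamic
#' branch,
#' \deqn{\mu(U) = w(U)\,\mu_b + (1 - w(U))\,c\,(\eta U)^p,}
#' where \eqn{w(U) = 1 / (1 + (U/U_t)^s)} is a logistic function of
#' \eqn{\log U} centred at the transition speed \eqn{U_t}.
#'
#' @param boundary_mu dimensionless boundary friction coefficient.
#' @param transition_speed m/s, centre of the boundary-to-mixed transition.
#' @param transition_sharpness dimensionless logistic steepness in
#'   \eqn{\log U}.
#' @param hydrodynamic_coeff dimensionless prefactor of the hydrodynamic
#'   branch.
#' @param hydrodynamic_exponent exponent \eqn{p \in (0, 1]} of the
#'   hydrodynamic branch.
#' @param viscosity_at_contact Pa.s, lubricant viscosity entering the
#'   hydrodynamic branch.
#' @param speed_range length-2 numeric, entrainment-speed window in m/s
#'   (default 0.0035 to 1, the ball-on-disc sweep).
#' @param n_points samples, log-spaced over `speed_range`.
#' @param noise_cv multiplicative noise CV (default 0.02).
#' @return An object of class `stribeck_params`.
#' @export
stribeck_params <- function(boundary_mu, transition_speed,
                            transition_sharpness = 6,
                            hydrodynamic_coeff = 0.7,
                            hydrodynamic_exponent = 0.5,
                            viscosity_at_contact = 0.01,
                            speed_range = c(0.0035, 1.0),
                            n_points = 30L, noise_cv = 0.02) {
  check_number(boundary_mu, "boundary_mu", positive = TRUE)
  check_number(transition_speed, "transition_speed", positive = TRUE)
  check_number(transition_sharpness, "transition_sharpness", positive = TRUE)
  check_number(hydrodynamic_coeff, "hydrodynamic_coeff", positive = TRUE)
  check_number(hydrodynamic_exponent, "hydrodynamic_exponent",
               positive = TRUE)
  if (hydrodynamic_exponent > 1)
    stop_param("hydrodynamic_exponent must be in (0, 1]")
  check_number(viscosity_at_contact, "viscosity_at_contact", positive = TRUE)
  if (length(speed_range) != 2L || any(speed_range <= 0) ||
      diff(speed_range) <= 0)
    stop_param("speed_range must be strictly positive and increasing")
  check_number(noise_cv, "noise_cv", nonneg = TRUE)
  if (n_points < 4L) stop_param("n_points must be >= 4")
  structure(list(boundary_mu = boundary_mu,
                 transition_speed = transition_speed,
                 transition_sharpness = transition_sharpness,
                 hydrodynamic_coeff = hydrodynamic_coeff,
                 hydrodynamic_exponent = hydrodynamic_exponent,
                 viscosity_at_contact = viscosity_at_contact,
                 speed_range = as.numeric(speed_range),
                 n_points = as.integer(n_points), noise_cv = noise_cv),
            class = "stribeck_params")
}

#' Parameters for a synthetic QCM-D frequency trace
#'
#' Emulates the resonance-frequency shift of a coated quartz sensor during
#' lubricant injection and buffer rinse: a flat baseline, an exponential
#' adsorption transient towards \eqn{-|\Delta f|_{plateau}}, and after the
#' rinse an exponential relaxation towards
#' \eqn{-|\Delta f|_{plateau}(1 - r)} where \eqn{r} is the removed
#' fraction. Counter noise is additive Gaussian.
#'
#' @param plateau_shift Hz, magnitude of the adsorption-saturation shift
#'   \eqn{|\Delta f|}.
#' @param adsorption_tau s, adsorption time constant.
#' @param injection_time s, sample injection into the chamber.
#' @param rinse_time s, buffer injection (must exceed `injection_time`).
#' @param removal_fraction fraction of the layer removed by rinsing, in
#'   [0, 1].
#' @param desorption_tau s, desorption time constant (default 60).
#' @param baseline_noise_sd Hz, additive Gaussian noise sd (default 0.5).
#' @param sampling_interval s (default 2).
#' @param duration s, total trace length (must exceed `rinse_time`;
#'   default `rinse_time + 600`).
#' @return An object of class `qcmd_params`.
#' @export
qcmd_params <- function(plateau_shift, adsorption_tau, injection_time,
                        rinse_time, removal_fraction, desorption_tau = 60,
                        baseline_noise_sd = 0.5, sampling_interval = 2,
                        duration = rinse_time + 600) {
  check_number(plateau_shift, "plateau_shift", positive = TRUE)
  check_number(adsorption_tau, "adsorption_tau", positive = TRUE)
  check_number(injection_time, "injection_time", nonneg = TRUE)
  check_number(rinse_time, "rinse_time", positive = TRUE)
  if (rinse_time <= injection_time)
    stop_param("rinse_time (%g) must exceed injection_time (%g)",
               rinse_time, injection_time)
  check_number(removal_fraction, "removal_fraction", nonneg = TRUE)
  if (removal_fraction > 1) stop_param("removal_fraction must be in [0, 1]")
  check_number(desorption_tau, "desorption_tau", positive = TRUE)
  check_number(baseline_noise_sd, "baseline_noise_sd", nonneg = TRUE)
  check_number(sampling_interval, "sampling_interval", positive = TRUE)
  check_number(duration, "duration", positive = TRUE)
  if (duration <= rinse_time)
    stop_param("duration (%g) must exceed rinse_time (%g)",
               duration, rinse_time)
  structure(list(plateau_shift = plateau_shift,
                 adsorption_tau = adsorption_tau,
                 injection_time = injection_time, rinse_time = rinse_time,
                 removal_fraction = removal_fraction,
                 desorption_tau = desorption_tau,
                 baseline_noise_sd = baseline_noise_sd,
                 sampling_interval = sampling_interval, duration = duration),
            class = "qcmd_params")
}

#' Preset parameter sets for the four benchmark classes
#'
#' Returns generator parameters whose noiseless summary statistics fall in
#' the measured ranges reported for a representative product of each
#' format category: a `liquid` (spray-like, Boots-type), a
#' `viscous_liquid` (BioXtra-type), a `gel` (Oralieve-type) and diluted
#' human `saliva`. Anchors: apparent shear viscosity at 50 1/s of 0.025,
#' 0.548, 5.4 and 0.0025 Pa.s; breakup times of order 0.03, 0.31, 24 and
#' 2 s; QCM-D plateaus of 20.6, 21.6, 50.0 and 63.6 Hz with removal
#' fractions 0.28, 0.23, 0.46 and 0.04.
#'
#' @param name one of `"liquid"`, `"viscous_liquid"`, `"gel"`, `"saliva"`.
#' @return A list with elements `flow`, `thinning`, `stribeck`, `qcmd`
#'   (the four parameter objects), `sigma` (surface tension, N/m) and
#'   `expected_class` (the viscosity class the preset is built to land
#'   in).
#' @examples
#' p <- preset_params("gel")
#' p$expected_class
#' @export
preset_params <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("liquid", "viscous_liquid", "gel", "saliva"))
    sb_stop("salivabench_lookup_error",
            "unknown preset '%s'; expected one of liquid, viscous_liquid, gel, saliva",
            as.character(name)[1L])
  switch(name,
    liquid = list(
      # spray-like: eta(50/s) ~ 0.025 Pa.s, elastic filament, t_b ~ 0.03 s
      flow = flow_curve_params(0.5, 0.013, 2.0, 0.8),
      thinning = thinning_params("elastic", lambda_c = 1.637e-3,
                                 sigma = 0.055, initial_plateau = 0.002,
                                 sampling_rate = 10000, duration = 0.035),
      stribeck = stribeck_params(boundary_mu = 0.40,
                                 transition_speed = 0.06,
                                 viscosity_at_contact = 0.025,
                                 hydrodynamic_coeff = 0.8),
      qcmd = qcmd_params(plateau_shift = 20.6, adsorption_tau = 184,
                         injection_time = 300,
                         rinse_time = 300 + 6.5 * 184,
                         removal_fraction = 0.28),
      sigma = 0.055, expected_class = "liquid"),
    viscous_liquid = list(
      # BioXtra-like: low-rate plateau ~1.6 Pa.s, eta(50/s) ~ 0.548 Pa.s,
      # power-law filament with t_b = 0.31 s
      flow = flow_curve_params(1.6, 0.05, 0.1, 0.464),
      thinning = thinning_params("power_law", K = 0.5, n = 1, t_b = 0.31,
                                 sigma = 0.06, initial_plateau = 0.15,
                                 sampling_rate = 2000),
      stribeck = stribeck_params(boundary_mu = 0.07,
                                 transition_speed = 0.04,
                                 viscosity_at_contact = 0.548),
      qcmd = qcmd_params(plateau_shift = 21.6, adsorption_tau = 828,
                         injection_time = 300,
                         rinse_time = 300 + 6.5 * 828,
                         removal_fraction = 0.23, sampling_interval = 4),
      sigma = 0.06, expected_class = "viscous_liquid"),
    gel = list(
      # gel: three-decade shear thinning, eta(50/s) ~ 5.4 Pa.s,
      # long-lived filament t_b ~ 24.25 s
      flow = flow_curve_params(600, 0.05, 3.75, 0.9),
      thinning = thinning_params("power_law", K = 30, n = 0.7, t_b = 24.25,
                                 sigma = 0.06, initial_plateau = 0.25,
                                 sampling_rate = 100),
      stribeck = stribeck_params(boundary_mu = 0.012,
                                 transition_speed = 0.02,
                                 viscosity_at_contact = 5.4,
                                 hydrodynamic_coeff = 0.15),
      qcmd = qcmd_params(plateau_shift = 50.0, adsorption_tau = 200,
                         injection_time = 300,
                         rinse_time = 300 + 6.5 * 200,
                         removal_fraction = 0.46),
      sigma = 0.06, expected_class = "gel"),
    saliva = list(
      # diluted human saliva: eta(50/s) ~ 2.5e-3 Pa.s, elastic filament
      # with t_b ~ 2 s, strong adsorption (63.6 Hz) and 4% removal
      flow = flow_curve_params(8e-3, 2e-3, 0.2, 1.0),
      thinning = thinning_params("elastic", lambda_c = 0.1111,
                                 sigma = 0.053, initial_plateau = 0.1,
                                 sampling_rate = 500),
      stribeck = stribeck_params(boundary_mu = 0.02,
                                 transition_speed = 0.03,
                                 viscosity_at_contact = 0.0025,
                                 hydrodynamic_coeff = 0.3),
      qcmd = qcmd_params(plateau_shift = 63.6, adsorption_tau = 460.1,
                         injection_time = 300,
                         rinse_time = 300 + 6.5 * 460.1,
                         removal_fraction = 0.04, sampling_interval = 3),
      sigma = 0.053, expected_class = "liquid"))
}
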
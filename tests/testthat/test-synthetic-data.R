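# Synthetic instrument generators: closed-form agreement, determinism,
# censoring, parameter validation.

test_that("flow-curve generator follows the Cross law and its degenerate limits", {
  # Newtonian degenerate case: both plateaus equal -> flat curve
  p <- flow_curve_params(0.5, 0.5, 1, 1, noise_cv = 0, n_replicates = 1L)
  fc <- generate_flow_curve(p, 1L)[[1L]]
  expect_equal(fc$viscosity, rep(0.5, p$n_points))

  # gel preset, noiseless: value at 50 1/s equals the analytic model value
  g <- noiseless(preset_params("gel")$flow)
  fc <- generate_flow_curve(g, 1L)[[1L]]
  eta50_analytic <- 0.05 + (600 - 0.05) / (1 + (3.75 * 50)^0.9)
  # 50 1/s is not a grid node, so allow for log-log interpolation error
  expect_equal(viscosity_at(fc, 50), eta50_analytic, tolerance = 1e-4)
  expect_equal(cross_viscosity(g, 50), eta50_analytic, tolerance = 1e-12)

  # noiseless generators agree with the law everywhere to < 1e-12
  for (nm in names(preset_classes)) {
    p <- noiseless(preset_params(nm)$flow)
    fc <- generate_flow_curve(p, 3L)[[1L]]
    expect_lt(max(abs(fc$viscosity / cross_viscosity(p, fc$shear_rate) - 1)),
              1e-12)
  }
})

test_that("generators are deterministic given (params, seed)", {
  p <- preset_params("viscous_liquid")
  expect_identical(generate_flow_curve(p$flow, 7L),
                   generate_flow_curve(p$flow, 7L))
  expect_identical(generate_thinning_trace(p$thinning, 7L),
                   generate_thinning_trace(p$thinning, 7L))
  expect_identical(generate_friction_curve(p$stribeck, 7L),
                   generate_friction_curve(p$stribeck, 7L))
  expect_identical(generate_qcmd_trace(p$qcmd, 7L),
                   generate_qcmd_trace(p$qcmd, 7L))
  # different seeds differ only within noise
  a <- generate_flow_curve(p$flow, 1L)[[1L]]
  b <- generate_flow_curve(p$flow, 2L)[[1L]]
  expect_false(identical(a$viscosity, b$viscosity))
  expect_identical(a$shear_rate, b$shear_rate)
  expect_lt(max(abs(log(a$viscosity / b$viscosity))), 10 * 0.02 * 2)
  # generators leave the caller's RNG state untouched
  set.seed(99); before <- .Random.seed
  invisible(generate_qcmd_trace(p$qcmd, 5L))
  expect_identical(.Random.seed, before)
})

test_that("thinning generator matches its closed-form laws and censors at the floor", {
  # elastic, noiseless: ln D linear in t with slope -1/(3 lambda_c)
  tp <- thinning_params("elastic", lambda_c = 0.05, sigma = 0.06,
                        noise_cv = 0, initial_plateau = 0.05,
                        sampling_rate = 1000)
  tr <- generate_thinning_trace(tp, 1L)
  post <- tr$time > 0.05 & tr$diameter > tr$resolution
  fit <- lm(log(tr$diameter[post]) ~ tr$time[post])
  expect_equal(unname(coef(fit)[2L]), -1 / (3 * 0.05), tolerance = 1e-9)

  # power law, n = 1: linear decay reaching the floor at
  # t_b - resolution * K / (2 phi0 sigma)
  pp <- thinning_params("power_law", K = 0.5, n = 1, t_b = 0.31,
                        sigma = 0.06, initial_plateau = 0.15,
                        noise_cv = 0, sampling_rate = 5000)
  tr <- generate_thinning_trace(pp, 1L)
  t_floor <- 0.31 - 20e-6 * 0.5 / (2 * 0.142 * 0.06)
  first_floor <- tr$time[which(tr$diameter <= tr$resolution)[1L]]
  expect_lt(abs(first_floor - t_floor), 1 / 5000 + 1e-12)
  # at and beyond t_b the diameter sits at the resolution floor
  expect_true(all(tr$diameter[tr$time >= 0.31] == tr$resolution))
  # noiseless law agreement over the uncensored region
  law <- salivabench:::thinning_law(pp, tr$time)
  open <- tr$diameter > tr$resolution
  expect_lt(max(abs(tr$diameter[open] / law[open] - 1)), 1e-12)
})

test_that("thinning parameter validation enforces the model's physical limits", {
  # power-law diameter exceeding the plate at the end of the plateau
  expect_error(thinning_params("power_law", K = 0.5, n = 1, t_b = 0.31,
                               sigma = 0.06, initial_plateau = 0.01),
               class = "salivabench_parameter_error")
  expect_error(thinning_params("elastic", lambda_c = 0.05, K = 1,
                               sigma = 0.06),
               class = "salivabench_parameter_error")
  expect_error(thinning_params("power_law", K = 0.5, n = 1.8, t_b = 1,
                               sigma = 0.06),
               class = "salivabench_parameter_error")
  expect_error(thinning_params("power_law", K = 0.5, n = 1, t_b = 0.1,
                               sigma = 0.06, initial_plateau = 0.2),
               class = "salivabench_parameter_error")
})

test_that("Stribeck generator has the declared plateau and hydrodynamic limits", {
  sp <- stribeck_params(boundary_mu = 0.3, transition_speed = 0.05,
                        transition_sharpness = 8,
                        hydrodynamic_coeff = 0.7,
                        hydrodynamic_exponent = 0.5,
                        viscosity_at_contact = 0.02,
                        speed_range = c(1e-4, 10), n_points = 60L,
                        noise_cv = 0)
  fc <- generate_friction_curve(sp, 1L)
  low <- fc$speed < 0.05 / 20
  expect_true(all(abs(fc$mu[low] / 0.3 - 1) < 0.01))
  high <- fc$speed > 0.05 * 20
  hydro <- 0.7 * (0.02 * fc$speed[high])^0.5
  expect_true(all(abs(fc$mu[high] / hydro - 1) < 0.01))
  # doubling the viscosity multiplies the hydrodynamic branch by 2^p
  sp2 <- sp; sp2$viscosity_at_contact <- 0.04
  fc2 <- generate_friction_curve(sp2, 1L)
  i <- length(fc$speed)   # far into the hydrodynamic branch
  expect_equal(fc2$mu[i] / fc$mu[i], 2^0.5, tolerance = 1e-3)
  expect_error(stribeck_params(boundary_mu = -1, transition_speed = 0.05),
               class = "salivabench_parameter_error")
})

test_that("QCM-D generator follows the adsorption/desorption kinetics", {
  base <- qcmd_params(plateau_shift = 50, adsorption_tau = 100,
                      injection_time = 200, rinse_time = 1800,
                      removal_fraction = 0.3, baseline_noise_sd = 0)
  tr <- generate_qcmd_trace(base, 1L)
  # value one time constant after injection: -A (1 - 1/e)
  i <- which.min(abs(tr$time - 300))
  expect_equal(tr$delta_f[i], -50 * (1 - exp(-1)), tolerance = 1e-9)
  # removal 0: pre- and post-rinse plateaus equal
  p0 <- base; p0$removal_fraction <- 0
  pl <- plateau_frequencies(generate_qcmd_trace(p0, 1L))
  expect_equal(unname(pl["delta_f_before"]), unname(pl["delta_f_after"]),
               tolerance = 1e-6)
  # removal 1: post-rinse plateau returns to baseline (within the tail of
  # the desorption transient inside the trailing window)
  p1 <- base; p1$removal_fraction <- 1
  pl <- plateau_frequencies(generate_qcmd_trace(p1, 1L))
  expect_lt(unname(pl["delta_f_after"]), 0.05)
  expect_error(qcmd_params(plateau_shift = 50, adsorption_tau = 100,
                           injection_time = 200, rinse_time = 1800,
                           removal_fraction = 0.3, duration = 1000),
               class = "salivabench_parameter_error")
})

test_that("generated series are finite, ordered and unit-consistent", {
  for (nm in names(preset_classes)) {
    p <- preset_params(nm)
    fc <- generate_flow_curve(p$flow, 5L)[[1L]]
    expect_true(all(is.finite(fc$shear_rate)) && all(diff(fc$shear_rate) > 0))
    tr <- generate_thinning_trace(p$thinning, 5L)
    expect_true(all(is.finite(tr$diameter)) && all(diff(tr$time) > 0))
    expect_true(all(tr$diameter >= tr$resolution))
    st <- generate_friction_curve(p$stribeck, 5L)
    expect_true(all(is.finite(st$mu)) && all(diff(st$speed) > 0))
    qc <- generate_qcmd_trace(p$qcmd, 5L)
    expect_true(all(is.finite(qc$delta_f)) && all(diff(qc$time) > 0))
  }
})

test_that("presets carry the anchor statistics of their product class", {
  expect_error(preset_params("syrup"), class = "salivabench_lookup_error")
  # liquid preset breaks up at ~0.03 s
  tp <- noiseless(preset_params("liquid")$thinning)
  expect_equal(detect_breakup(generate_thinning_trace(tp, 1L)), 0.03,
               tolerance = 0.05)
  # saliva preset loses ~4% of its layer on rinsing
  qp <- preset_params("saliva")$qcmd
  expect_equal(qp$removal_fraction, 0.04)
  # gel preset is classified as a gel from its own noiseless flow curve
  g <- noiseless(preset_params("gel")$flow)
  eta <- viscosity_at(generate_flow_curve(g, 1L)[[1L]], 50)
  expect_identical(classify_viscosity(eta)$label, "gel")
})
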
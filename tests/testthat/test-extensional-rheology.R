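# CaBER analysis: breakup detection, elastic and power-law fits, model
# selection, and the strain / strain-rate / extensional-viscosity /
# Trouton pipeline.

test_that("detect_breakup finds the sustained resolution-floor crossing", {
  pp <- thinning_params("power_law", K = 0.5, n = 1, t_b = 0.31,
                        sigma = 0.06, initial_plateau = 0.15,
                        noise_cv = 0, sampling_rate = 5000)
  tr <- generate_thinning_trace(pp, 1L)
  t_floor <- 0.31 - 20e-6 * 0.5 / (2 * 0.142 * 0.06)
  expect_lt(abs(detect_breakup(tr) - t_floor), 1 / 5000 + 1e-12)

  # monotone trace ending above the floor: no breakup
  tr <- thinning_trace(seq(0, 1, 0.01), seq(3e-3, 1e-3, length.out = 101))
  expect_true(is.na(detect_breakup(tr)))

  # a single noise dip below the floor is ignored; the sustained crossing wins
  d <- c(seq(3e-3, 1e-4, length.out = 50), 1.9e-5,
         seq(9e-5, 3e-5, length.out = 20), rep(2e-5, 30))
  t <- seq_along(d) * 0.01
  tr <- thinning_trace(t, d)
  expect_equal(detect_breakup(tr), t[72L])  # first point of the final floor run
})

test_that("fit_elastic recovers the relaxation time", {
  tr <- reference_elastic_trace(lambda_c = 0.05, noise_cv = 0)
  fit <- fit_elastic(tr)
  expect_equal(fit$lambda_c, 0.05, tolerance = 1e-3)
  expect_lt(fit$rms_log_residual, 1e-8)
  # 2% multiplicative noise: within 5% of truth (spot-check seeds; the
  # 50-seed median is exercised in the acceptance suite)
  errs <- vapply(1:10, function(s) {
    fit <- fit_elastic(reference_elastic_trace(lambda_c = 0.05,
                                               noise_cv = 0.02, seed = s))
    abs(fit$lambda_c / 0.05 - 1)
  }, numeric(1L))
  expect_lt(median(errs), 0.05)
  # constant-diameter trace: no decay to fit
  tr <- thinning_trace(seq(0, 1, 0.01), rep(3e-3, 101))
  expect_error(fit_elastic(tr), class = "salivabench_fit_error")
})

test_that("fit_power_law recovers (K, n, t_b) and honours the model structure", {
  pp <- thinning_params("power_law", K = 0.5, n = 1, t_b = 0.31,
                        sigma = 0.06, initial_plateau = 0.15,
                        noise_cv = 0, sampling_rate = 2000)
  tr <- generate_thinning_trace(pp, 1L)
  fit <- fit_power_law(tr, 0.06)
  expect_equal(fit$K, 0.5, tolerance = 0.005)
  expect_equal(fit$n, 1.0, tolerance = 0.005)
  expect_equal(fit$t_b, 0.31, tolerance = 0.005)
  # the fitted model evaluates to zero diameter at t_b
  expect_equal(predict(fit, fit$t_b), 0)
  # Eq depends on sigma/K only: doubling both leaves the curve unchanged,
  # so fitting with doubled sigma doubles the recovered K
  fit2 <- fit_power_law(tr, 0.12)
  expect_equal(fit2$K, 2 * fit$K, tolerance = 1e-6)
  expect_equal(fit2$n, fit$n, tolerance = 1e-6)
  expect_equal(predict(fit2, tr$time), predict(fit, tr$time),
               tolerance = 1e-6)
  # a fractional exponent is recovered too
  pp <- thinning_params("power_law", K = 30, n = 0.7, t_b = 24.25,
                        sigma = 0.06, initial_plateau = 0.25,
                        noise_cv = 0, sampling_rate = 100)
  fit <- fit_power_law(generate_thinning_trace(pp, 1L), 0.06)
  expect_equal(fit$n, 0.7, tolerance = 0.005)
  expect_equal(fit$t_b, 24.25, tolerance = 0.005)
})

test_that("model selection prefers the lower-residual thinning model", {
  el <- reference_elastic_trace(noise_cv = 0.01, seed = 3L)
  expect_identical(select_thinning_model(el, 0.06)$choice, "elastic")
  pp <- noiseless(preset_params("gel")$thinning)
  pw <- generate_thinning_trace(pp, 3L)
  sel <- select_thinning_model(pw, 0.06)
  expect_identical(sel$choice, "power_law")
  # when only one model converges, it is chosen
  expect_true(sel$choice %in% c("elastic", "power_law"))
  short <- thinning_trace(seq(0, 1, 0.01), rep(3e-3, 101))
  expect_error(select_thinning_model(short, 0.06),
               class = "salivabench_analysis_error")
})

test_that("strain follows the Hencky definition and is unit-invariant", {
  expect_equal(hencky_strain(6e-3, 6e-3), 0)
  expect_equal(hencky_strain(20e-6, 6e-3), 11.4076, tolerance = 1e-4)
  # ratio inside the log: any common unit cancels
  expect_equal(hencky_strain(20e-6, 6e-3), hencky_strain(20e-3, 6))
})

test_that("extensional pipeline matches the elastic closed form away from edges", {
  lam <- 0.05; sig <- 0.06
  tr <- reference_elastic_trace(lambda_c = lam, sigma = sig, noise_cv = 0)
  prof <- extensional_profile(tr, sig)
  p <- prof$profile
  v <- which(p$valid)
  inner <- v[v > min(v) + 30 & v < max(v) - 30]
  # strain rate is the constant 2 / (3 lambda_c)
  expect_lt(max(abs(p$strain_rate[inner] / (2 / (3 * lam)) - 1)), 0.005)
  # eta_E = (2 sigma / D) * 3 lambda_c / 2
  eta_sym <- 3 * lam * sig / p$diameter[inner]
  expect_lt(max(abs(p$eta_extensional[inner] / eta_sym - 1)), 0.005)
})

test_that("extensional pipeline is exact for linear power-law thinning", {
  pp <- thinning_params("power_law", K = 0.5, n = 1, t_b = 0.31,
                        sigma = 0.06, initial_plateau = 0.15,
                        noise_cv = 0, sampling_rate = 2000)
  tr <- generate_thinning_trace(pp, 1L)
  prof <- extensional_profile(tr, 0.06)
  p <- prof$profile
  v <- which(p$valid)
  inner <- v[v > min(v) + 5 & v < max(v) - 5]
  # for n = 1 the apparent extensional viscosity is the constant K / (2 phi0)
  expect_lt(max(abs(p$eta_extensional[inner] / (0.5 / (2 * 0.142)) - 1)),
            1e-6)
  expect_equal(prof$max_eta_extensional, 0.5 / (2 * 0.142),
               tolerance = 1e-6)
})

test_that("extensional viscosity scales linearly with surface tension", {
  tr <- reference_elastic_trace(noise_cv = 0.02, seed = 9L)
  a <- extensional_profile(tr, 0.06)
  b <- extensional_profile(tr, 0.18)
  expect_equal(b$profile$eta_extensional, 3 * a$profile$eta_extensional,
               tolerance = 1e-12)
  expect_equal(b$max_eta_extensional, 3 * a$max_eta_extensional,
               tolerance = 1e-12)
})

test_that("the Trouton denominator is the shear model at the strain rate", {
  sfit <- fit_shear_model(generate_flow_curve(
    noiseless(preset_params("viscous_liquid")$flow), 1L)[[1L]])
  tr <- reference_elastic_trace(lambda_c = 0.05, sigma = 0.06)
  prof <- extensional_profile(tr, 0.06, sfit)
  p <- prof$profile
  v <- p$valid
  expect_equal(p$trouton[v],
               p$eta_extensional[v] / predict(sfit, p$strain_rate[v]))
  # strain is non-decreasing while the filament thins
  expect_true(all(diff(p$strain[v]) > -1e-9))
  expect_error(extensional_profile(
    thinning_trace(seq(0, 1, 0.1), rep(3e-3, 11)), 0.06),
    class = "salivabench_analysis_error")
})
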
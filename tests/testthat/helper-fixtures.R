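# Shared fixtures: noiseless variants of the preset parameter sets, built
# in code at test time.

noiseless <- function(p) {
  if (inherits(p, "qcmd_params")) p$baseline_noise_sd <- 0
  else p$noise_cv <- 0
  p
}

preset_classes <- c(liquid = "liquid", viscous_liquid = "viscous_liquid",
                    gel = "gel", saliva = "liquid")

# Elastocapillary reference trace used by several extensional tests.
reference_elastic_trace <- function(lambda_c = 0.05, sigma = 0.06,
                                    noise_cv = 0, seed = 1L,
                                    sampling_rate = 1000) {
  tp <- thinning_params("elastic", lambda_c = lambda_c, sigma = sigma,
                        noise_cv = noise_cv, initial_plateau = 0.05,
                        sampling_rate = sampling_rate)
  generate_thinning_trace(tp, seed)
}
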
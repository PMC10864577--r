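# Shared fixture builders. Everything is generated in code at test time.

config_with <- function(defaults, overrides) {
  do.call(generator_config, utils::modifyList(defaults, overrides))
}

# Small, quiet dataset: three informative bands, no disturbances.
clean_config <- function(n_samples = 60, seed = 101, ...) {
  config_with(
    list(
      n_samples = n_samples,
      band_centers = c(600, 680, 840),
      band_widths = c(30, 25, 35),
      band_depths = c(0.10, 0.08, 0.12),
      band_couplings = c(0.010, 0.012, 0.015),
      gain_sd = 0, drift_offset_sd = 0, drift_slope_sd = 0, noise_sd = 0,
      sample_noise_sd = 0,
      seed = seed
    ),
    list(...)
  )
}

# Same bands with the default disturbances switched on.
noisy_config <- function(n_samples = 60, seed = 101, ...) {
  config_with(
    list(
      n_samples = n_samples,
      band_centers = c(600, 680, 840),
      band_widths = c(30, 25, 35),
      band_depths = c(0.10, 0.08, 0.12),
      band_couplings = c(0.010, 0.012, 0.015),
      seed = seed
    ),
    list(...)
  )
}

# Coarse wavelength grid keeps p small for oracle comparisons.
tiny_config <- function(n_samples = 30, seed = 7, p_step = 50, ...) {
  config_with(
    list(
      n_samples = n_samples, wavelength_step = p_step,
      band_centers = c(600, 840), band_widths = c(60, 70),
      band_depths = c(0.10, 0.12), band_couplings = c(0.012, 0.015),
      gain_sd = 0, drift_offset_sd = 0, drift_slope_sd = 0, noise_sd = 0.004,
      sample_noise_sd = 0,
      seed = seed
    ),
    list(...)
  )
}

rand_matrix <- function(n, p, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p)
}
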
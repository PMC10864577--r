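# Synthetic Vis-NIR spectra generator. Emits per-sample reflectance spectra
# whose absorption-band depths are linearly coupled to soluble solids
# content (SSC), plus the acquisition disturbances that motivate spectral
# pre-processing: multiplicative scatter gain, linear baseline drift and
# high-frequency noise. Planted band positions are recorded as ground truth
# so wavelength-selector recovery is testable.

#' Configuration for the synthetic spectra generator
#'
#' Defaults reproduce the structure of a 116-fruit SSC study: SSC is
#' approximately normal with mean 13.148 and SD 1.025 % Brix, reflectance is
#' low-variance below 500 nm and high-variance above 750 nm, and
#' SSC-informative absorption features sit around 600-700 nm and above
#' 750 nm.
#'
#' @param n_samples Number of fruit samples.
#' @param wavelength_start,wavelength_stop,wavelength_step Wavelength grid in
#'   nm (default 450-1000 nm at 2.5 nm, 221 points).
#' @param ssc_mean,ssc_sd Mean and SD of SSC in % Brix; draws are truncated
#'   to positive values.
#' @param band_centers Centers (nm) of Gaussian absorption bands.
#' @param band_widths Gaussian SD (nm) of each band.
#' @param band_depths Baseline absorption depth of each band (reflectance
#'   units).
#' @param band_couplings Linear coefficient of each band's depth on
#'   standardized SSC; a band with coupling 0 carries no SSC signal.
#' @param gain_sd SD of the per-sample log-normal multiplicative scatter
#'   gain (log scale).
#' @param drift_offset_sd,drift_slope_sd SDs of the per-sample additive
#'   baseline drift: offset plus slope times normalized wavelength.
#' @param noise_sd SD of i.i.d. additive high-frequency noise.
#' @param sample_noise_sd SD of smooth, sample-specific spectral variation
#'   (a squared-exponential process in wavelength, scaled by the continuum
#'   level). This emulates between-fruit differences unrelated to SSC; it
#'   is what makes full-spectrum regression overfit and wavelength
#'   selection worthwhile, as on real spectra.
#' @param sample_noise_scale Correlation length (nm) of that variation.
#' @param low_wavelength_damping Factor in `[0, 1)` shrinking the continuum
#'   (hence its variance under multiplicative gain) below 500 nm.
#' @param seed Integer seed; a fixed seed yields a byte-identical dataset.
#' @return A list of class `generator_config`.
#' @export
#' @examples
#' cfg <- generator_config(n_samples = 30, seed = 7)
#' ds <- generate_spectra(cfg)
generator_config <- function(n_samples = 116,
                             wavelength_start = 450,
                             wavelength_stop = 1000,
                             wavelength_step = 2.5,
                             ssc_mean = 13.148,
                             ssc_sd = 1.025,
                             band_centers = c(600, 680, 840, 960),
                             band_widths = c(30, 25, 35, 30),
                             band_depths = c(0.10, 0.08, 0.12, 0.10),
                             band_couplings = c(0.010, 0.012, 0.015, 0.011),
                             gain_sd = 0.08,
                             drift_offset_sd = 0.02,
                             drift_slope_sd = 0.03,
                             noise_sd = 0.005,
                             sample_noise_sd = 0.05,
                             sample_noise_scale = 15,
                             low_wavelength_damping = 0.7,
                             seed = 1L) {
  if (n_samples <= 0) abort("`n_samples` must be a positive integer.")
  if (wavelength_step <= 0) abort("`wavelength_step` must be positive.")
  if (wavelength_stop <= wavelength_start) {
    abort("`wavelength_stop` must exceed `wavelength_start`.")
  }
  nb <- length(band_centers)
  if (length(band_widths) != nb || length(band_depths) != nb ||
      length(band_couplings) != nb) {
    abort("Band parameter vectors must all have the same length.")
  }
  sds <- c(gain_sd, drift_offset_sd, drift_slope_sd, noise_sd,
           sample_noise_sd, ssc_sd)
  if (any(sds < 0)) abort("All SDs must be non-negative.")
  if (sample_noise_scale <= 0) abort("`sample_noise_scale` must be positive.")
  if (low_wavelength_damping < 0 || low_wavelength_damping >= 1) {
    abort("`low_wavelength_damping` must be in [0, 1).")
  }
  structure(
    list(
      n_samples = as.integer(n_samples),
      wavelength_start = wavelength_start,
      wavelength_stop = wavelength_stop,
      wavelength_step = wavelength_step,
      ssc_mean = ssc_mean, ssc_sd = ssc_sd,
      band_centers = band_centers, band_widths = band_widths,
      band_depths = band_depths, band_couplings = band_couplings,
      gain_sd = gain_sd,
      drift_offset_sd = drift_offset_sd, drift_slope_sd = drift_slope_sd,
      noise_sd = noise_sd,
      sample_noise_sd = sample_noise_sd,
      sample_noise_scale = sample_noise_scale,
      low_wavelength_damping = low_wavelength_damping,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

config_wavelengths <- function(config) {
  seq(config$wavelength_start, config$wavelength_stop,
      by = config$wavelength_step)
}

# Smooth sigmoid continuum: low reflectance at 450 nm rising to a plateau
# near 780 nm, with an extra damping of the level below 500 nm so that the
# multiplicative gain produces the narrow-then-broad variance profile.
continuum_spectrum <- function(wavelengths, damping) {
  base <- 0.08 + 0.47 / (1 + exp(-(wavelengths - 650) / 60))
  damp <- 1 - damping / (1 + exp((wavelengths - 500) / 5))
  base * damp
}

# n x p matrix of noise-free spectra: continuum minus Gaussian absorption
# bands whose depths are affine in standardized SSC.
clean_spectra <- function(ssc, config) {
  wl <- config_wavelengths(config)
  cont <- continuum_spectrum(wl, config$low_wavelength_damping)
  z <- (ssc - config$ssc_mean) / config$ssc_sd
  X <- matrix(cont, nrow = length(ssc), ncol = length(wl), byrow = TRUE)
  for (b in seq_along(config$band_centers)) {
    shape <- exp(-(wl - config$band_centers[b])^2 /
                   (2 * config$band_widths[b]^2))
    depth <- config$band_depths[b] + config$band_couplings[b] * z
    X <- X - outer(depth, shape)
  }
  X
}

#' Apply acquisition disturbances to clean spectra
#'
#' Each row i becomes `gain_i * x_i + offset_i + slope_i * u + s_i + noise`,
#' where `u` is wavelength normalized to `[0, 1]`, `gain_i` is log-normal
#' (so reflectance stays positive-scaled), offset and slope are normal,
#' `s_i` is a smooth sample-specific deviation (squared-exponential
#' covariance in wavelength, amplitude proportional to the continuum
#' level), and the noise is i.i.d. normal. Setting all disturbance SDs to
#' zero returns the input exactly.
#'
#' @param clean n x p matrix of disturbance-free spectra.
#' @param config A [generator_config()].
#' @param seed Integer seed; defaults to a child of `config$seed`.
#' @return An n x p matrix.
#' @export
apply_disturbances <- function(clean, config,
                               seed = fanout_seed(config$seed, "disturbances")) {
  clean <- check_matrix(clean, "clean")
  n <- nrow(clean)
  p <- ncol(clean)
  u <- seq(0, 1, length.out = p)
  wl <- config_wavelengths(config)
  structured <- 0
  if (config$sample_noise_sd > 0) {
    # squared-exponential covariance in wavelength, scaled by the continuum
    # so low-signal regions stay quiet
    K <- exp(-outer(wl, wl, "-")^2 / (2 * config$sample_noise_scale^2))
    L <- chol(K + diag(1e-8, p))
    level <- continuum_spectrum(wl, config$low_wavelength_damping)
    level <- level / max(level)
  }
  with_seed(seed, {
    gain <- exp(rnorm(n, 0, config$gain_sd))
    offset <- rnorm(n, 0, config$drift_offset_sd)
    slope <- rnorm(n, 0, config$drift_slope_sd)
    if (config$sample_noise_sd > 0) {
      structured <- (matrix(rnorm(n * p), n, p) %*% L) *
        rep(config$sample_noise_sd * level, each = n)
    }
    noise <- matrix(rnorm(n * p, 0, config$noise_sd), n, p)
    gain * clean + offset + outer(slope, u) + structured + noise
  })
}

#' Generate a synthetic spectral dataset
#'
#' Draws SSC from a truncated normal, builds clean spectra whose absorption
#' band depths are linearly coupled to standardized SSC, then applies the
#' configured disturbances. Deterministic for a fixed `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A tibble of class `spectral_dataset` with columns `sample_id`,
#'   `ssc`, and one numeric column per wavelength (named by nm). Ground
#'   truth about the planted informative bands is stored in the `truth`
#'   attribute (see [spectra_truth()]).
#' @export
#' @examples
#' ds <- generate_spectra(generator_config(n_samples = 20, seed = 3))
#' dim(spectra_matrix(ds))
generate_spectra <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_samples
  wl <- config_wavelengths(config)

  ssc <- with_seed(fanout_seed(config$seed, "ssc"), {
    draw <- rnorm(n, config$ssc_mean, config$ssc_sd)
    # truncate to (0, Inf): redraw any non-positive values
    while (any(draw <= 0)) {
      bad <- draw <= 0
      draw[bad] <- rnorm(sum(bad), config$ssc_mean, config$ssc_sd)
    }
    draw
  })

  X <- apply_disturbances(clean_spectra(ssc, config), config)

  informative <- config$band_centers[config$band_couplings != 0]
  truth <- list(
    informative_centers = informative,
    informative_indices = vapply(
      informative, function(cc) which.min(abs(wl - cc)), integer(1)
    ),
    seed = config$seed,
    config = unclass(config)
  )
  new_spectral_dataset(
    sample_ids = sprintf("S%03d", seq_len(n)),
    wavelengths = wl, reflectance = X, ssc = ssc, truth = truth
  )
}

new_spectral_dataset <- function(sample_ids, wavelengths, reflectance, ssc,
                                 truth = NULL) {
  reflectance <- check_matrix(reflectance, "reflectance")
  stopifnot(
    length(sample_ids) == nrow(reflectance),
    length(ssc) == nrow(reflectance),
    length(wavelengths) == ncol(reflectance)
  )
  if (any(diff(wavelengths) <= 0)) abort("Wavelengths must be strictly ascending.")
  if (any(ssc <= 0)) abort("All `ssc` values must be strictly positive.")
  out <- tibble::as_tibble(as.data.frame(reflectance))
  names(out) <- format_wavelength(wavelengths)
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = sample_ids, ssc = ssc), out
  )
  attr(out, "wavelengths") <- wavelengths
  if (!is.null(truth)) attr(out, "truth") <- truth
  class(out) <- c("spectral_dataset", class(out))
  out
}

format_wavelength <- function(wl) {
  formatC(wl, format = "fg", digits = 15)
}

#' Accessors for spectral datasets
#'
#' `spectra_matrix()` returns the n x p reflectance matrix,
#' `spectra_wavelengths()` the wavelength grid in nm, `spectra_ssc()` the
#' SSC vector (% Brix), and `spectra_truth()` the planted-band ground truth
#' (or `NULL` for data read from disk without a sidecar).
#'
#' @param data A `spectral_dataset` tibble (or any wide data frame with
#'   `sample_id`, `ssc` and numeric wavelength columns).
#' @return See each description.
#' @export
spectra_matrix <- function(data) {
  cols <- setdiff(names(data), c("sample_id", "ssc"))
  m <- as.matrix(data[cols])
  rownames(m) <- data$sample_id
  colnames(m) <- cols
  storage.mode(m) <- "double"
  m
}

#' @rdname spectra_matrix
#' @export
spectra_wavelengths <- function(data) {
  wl <- attr(data, "wavelengths")
  if (is.null(wl)) {
    wl <- suppressWarnings(
      as.numeric(setdiff(names(data), c("sample_id", "ssc")))
    )
    if (anyNA(wl)) abort("Wavelength columns could not be parsed as numbers.")
  }
  wl
}

#' @rdname spectra_matrix
#' @export
spectra_ssc <- function(data) data$ssc

#' @rdname spectra_matrix
#' @export
spectra_truth <- function(data) attr(data, "truth")

#' @export
print.spectral_dataset <- function(x, ...) {
  wl <- spectra_wavelengths(x)
  cat(sprintf(
    "<spectral_dataset: %d samples x %d wavelengths (%g-%g nm)>\n",
    nrow(x), length(wl), min(wl), max(wl)
  ))
  NextMethod()
}
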
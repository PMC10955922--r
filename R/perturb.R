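#' Perturbation model configuration
#'
#' Four perturbation channels harden the training corpus against the
#' non-idealities of a real sensor: (i) slowly varying source power
#' fluctuation (multiplicative in transmittance), (ii) absorption bands of
#' unknown interfering gases, (iii) additive white detection noise and
#' (iv) baseline miscalibration from non-standard normalisation (low-order
#' polynomial in absorbance). Channels are applied in that order; each can
#' be disabled individually (a disabled channel is the identity).
#'
#' Default magnitudes bracket a realistic multipass-cell system: +/-2%
#' power drift with at most 3 sine cycles across the window, 0--3 unknown
#' bands of width 1--20 cm^-1 and depth up to 0.1 absorbance, white noise
#' whose sigma is resolved at dataset-generation time so that the
#' high-concentration gas's peak SNR is about 150, and a baseline
#' polynomial of order <= 2 with coefficients up to 0.05 absorbance.
#'
#' @param power_fluct_amplitude relative amplitude of the multiplicative
#'   power envelope.
#' @param power_fluct_max_cycles maximum sine cycles across the window.
#' @param unknown_band_count integer range `c(min, max)` of bands per sample.
#' @param unknown_band_width HWHM range of a band, cm^-1.
#' @param unknown_band_depth peak-absorbance range of a band.
#' @param noise_sigma white-noise standard deviation (absorbance), or `NULL`
#'   to auto-resolve from the unit spectra in [generate_dataset()].
#' @param baseline_poly_order maximum polynomial order of the baseline term.
#' @param baseline_amplitude coefficient bound of the baseline polynomial
#'   (absorbance).
#' @param enable_power,enable_unknown,enable_noise,enable_baseline channel
#'   switches.
#' @return An object of class `perturbation_config`.
#' @export
perturbation_config <- function(power_fluct_amplitude = 0.02,
                                power_fluct_max_cycles = 3,
                                unknown_band_count = c(0L, 3L),
                                unknown_band_width = c(1, 20),
                                unknown_band_depth = c(0, 0.1),
                                noise_sigma = NULL,
                                baseline_poly_order = 2,
                                baseline_amplitude = 0.05,
                                enable_power = TRUE,
                                enable_unknown = TRUE,
                                enable_noise = TRUE,
                                enable_baseline = TRUE) {
  stopifnot(power_fluct_amplitude >= 0, power_fluct_amplitude < 1,
            power_fluct_max_cycles > 0,
            length(unknown_band_count) == 2, unknown_band_count[1] >= 0,
            diff(unknown_band_count) >= 0,
            length(unknown_band_width) == 2, unknown_band_width[1] > 0,
            length(unknown_band_depth) == 2, unknown_band_depth[1] >= 0,
            baseline_poly_order >= 0, baseline_amplitude >= 0)
  if (!is.null(noise_sigma)) stopifnot(noise_sigma >= 0)
  structure(list(power_fluct_amplitude = power_fluct_amplitude,
                 power_fluct_max_cycles = power_fluct_max_cycles,
                 unknown_band_count = as.integer(unknown_band_count),
                 unknown_band_width = unknown_band_width,
                 unknown_band_depth = unknown_band_depth,
                 noise_sigma = noise_sigma,
                 baseline_poly_order = as.integer(baseline_poly_order),
                 baseline_amplitude = baseline_amplitude,
                 enable_power = enable_power,
                 enable_unknown = enable_unknown,
                 enable_noise = enable_noise,
                 enable_baseline = enable_baseline),
            class = "perturbation_config")
}

#' Apply the perturbation channels to one spectrum
#'
#' Applies, in order: power fluctuation (gain in transmittance space, i.e.
#' `alpha - log(gain)` in absorbance), additive unknown-absorber bands
#' (Gaussian or Lorentzian, truncated to zero beyond 5 widths of their
#' centre), additive white Gaussian noise, and the polynomial baseline
#' offset. Uses the current RNG state; seed outside for reproducibility.
#'
#' @param spectrum absorbance vector on `grid`.
#' @param cfg a [perturbation_config()] with a concrete `noise_sigma` if the
#'   noise channel is enabled.
#' @param grid the [spectral_grid()] the spectrum lives on (band widths are
#'   in cm^-1).
#' @return perturbed absorbance vector.
#' @export
apply_perturbations <- function(spectrum, cfg, grid) {
  stopifnot(inherits(cfg, "perturbation_config"),
            inherits(grid, "spectral_grid"),
            length(spectrum) == grid$n_points, all(is.finite(spectrum)))
  s <- spectrum
  n <- grid$n_points
  u <- seq(0, 1, length.out = n)
  if (cfg$enable_power && cfg$power_fluct_amplitude > 0) {
    cycles <- stats::runif(1, 0.5, cfg$power_fluct_max_cycles)
    phase <- stats::runif(1, 0, 2 * pi)
    gain <- 1 + cfg$power_fluct_amplitude * sin(2 * pi * cycles * u + phase)
    s <- s - log(gain)
  }
  if (cfg$enable_unknown && cfg$unknown_band_count[2] > 0) {
    k <- sample(seq(cfg$unknown_band_count[1], cfg$unknown_band_count[2]), 1)
    if (k > 0) {
      for (b in seq_len(k)) {
        center <- stats::runif(1, grid$start, grid$end)
        width <- stats::runif(1, cfg$unknown_band_width[1],
                              cfg$unknown_band_width[2])
        depth <- stats::runif(1, cfg$unknown_band_depth[1],
                              cfg$unknown_band_depth[2])
        d <- grid$nu - center
        shape <- if (stats::runif(1) < 0.5) {
          exp(-log(2) * (d / width)^2)            # Gaussian, HWHM = width
        } else {
          width^2 / (d^2 + width^2)               # Lorentzian, HWHM = width
        }
        shape[abs(d) > 5 * width] <- 0
        s <- s + depth * shape
      }
    }
  }
  if (cfg$enable_noise) {
    if (is.null(cfg$noise_sigma)) {
      stop("apply_perturbations: noise channel enabled but noise_sigma is ",
           "NULL; resolve it (generate_dataset does this automatically)")
    }
    if (cfg$noise_sigma > 0) s <- s + stats::rnorm(n, 0, cfg$noise_sigma)
  }
  if (cfg$enable_baseline && cfg$baseline_amplitude > 0) {
    coefs <- stats::runif(cfg$baseline_poly_order + 1,
                          -cfg$baseline_amplitude, cfg$baseline_amplitude)
    s <- s + drop(outer(u, seq(0, cfg$baseline_poly_order), `^`) %*% coefs)
  }
  s
}
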
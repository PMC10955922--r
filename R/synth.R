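#' Synthetic line-list and cross-section fixtures
#'
#' Generates stand-in spectroscopic inputs so the whole pipeline runs with no
#' database download. Two archetypes are provided: `"dense-narrow"` emulates
#' the dense overlapping rovibrational line structure of small molecules
#' (methane- or water-like) as a [line_list()] with random Voigt parameters;
#' `"broad-band"` emulates a smooth multi-hump composite band (acetone-like)
#' as a [cross_section_table()]. Both are synthetic: line positions and
#' strengths are drawn at random, not taken from any database.
#'
#' @param archetype `"dense-narrow"` or `"broad-band"`.
#' @param window length-2 wavenumber window (cm^-1) inside which features are
#'   placed.
#' @param seed integer seed; output is a pure function of the arguments.
#' @param gas_id identifier for the product.
#' @param n_lines_range dense-narrow: range the line count is drawn from.
#' @param intensity_range dense-narrow: log-uniform line-intensity range,
#'   cm^-1/(molecule cm^-2).
#' @param molar_mass dense-narrow: molar mass, g/mol.
#' @param n_humps_range broad-band: range of the Gaussian hump count.
#' @param peak_value broad-band: maximum absorbance per (ppm m), base 10.
#' @return a [line_list()] or [cross_section_table()] depending on archetype.
#' @export
synth_linelist <- function(archetype = c("dense-narrow", "broad-band"),
                           window = c(2950, 3150), seed = 1,
                           gas_id = "synthetic",
                           n_lines_range = c(50, 500),
                           intensity_range = c(1e-24, 1.5e-21),
                           molar_mass = 16.04,
                           n_humps_range = c(2, 5),
                           peak_value = 2e-5) {
  archetype <- match.arg(archetype)
  stopifnot(length(window) == 2, window[2] > window[1])
  set.seed(seed)
  if (archetype == "dense-narrow") {
    n <- sample(seq(n_lines_range[1], n_lines_range[2]), 1)
    lines <- data.frame(
      center = stats::runif(n, window[1], window[2]),
      intensity = exp(stats::runif(n, log(intensity_range[1]),
                                   log(intensity_range[2]))),
      air_hwhm = stats::runif(n, 0.04, 0.08),
      self_hwhm = stats::runif(n, 0.05, 0.10),
      lower_state_energy = stats::runif(n, 0, 1500),
      temp_exponent = stats::runif(n, 0.5, 0.8),
      pressure_shift = stats::runif(n, -0.01, 0.01))
    line_list(gas_id, lines, molar_mass = molar_mass)
  } else {
    n_humps <- sample(seq(n_humps_range[1], n_humps_range[2]), 1)
    centers <- stats::runif(n_humps, window[1], window[2])
    widths <- stats::runif(n_humps, 10, 40)       # Gaussian sd, cm^-1
    amps <- stats::runif(n_humps, 0.3, 1) * peak_value
    margin <- 10
    nu <- seq(window[1] - margin, window[2] + margin, by = 0.25)
    vals <- numeric(length(nu))
    for (h in seq_len(n_humps)) {
      vals <- vals + amps[h] * exp(-(nu - centers[h])^2 / (2 * widths[h]^2))
    }
    cross_section_table(nu, vals, gas_id = gas_id)
  }
}

#' Synthetic three-gas unit-spectrum set
#'
#' Builds the fixture analogue of the methane/acetone/water unit spectra:
#' two dense-narrow line lists with distinct line placements and strengths
#' (a strong trace-gas absorber and a weaker but denser high-concentration
#' absorber) and one broad smooth band, all evaluated on the shared grid
#' under the given conditions. Intensity scales are chosen so that typical
#' mixtures (trace gases at tens of ppm, the water-like gas at 1000--2000
#' ppm over a 580 m path) reach peak absorbances of order 0.1--1, matching
#' realistic multipass-cell spectra.
#'
#' @param grid a [spectral_grid()].
#' @param cond an [env_conditions()].
#' @param seed integer seed for the fixture draw.
#' @return named list of three [unit_absorbance()] objects
#'   (`methane_like`, `acetone_like`, `water_like`), in the gas order used
#'   by labels throughout the package.
#' @export
fixture_unit_spectra <- function(grid = default_grid(),
                                 cond = env_conditions(), seed = 1) {
  win <- c(grid$start - 5, grid$end + 5)
  ll_m <- synth_linelist("dense-narrow", window = win, seed = seed + 101,
                         gas_id = "methane_like",
                         n_lines_range = c(80, 200),
                         intensity_range = c(1e-23, 1.5e-21),
                         molar_mass = 16.04)
  xs_a <- synth_linelist("broad-band", window = win, seed = seed + 202,
                         gas_id = "acetone_like", peak_value = 2e-5)
  ll_w <- synth_linelist("dense-narrow", window = win, seed = seed + 303,
                         gas_id = "water_like",
                         n_lines_range = c(200, 500),
                         intensity_range = c(1e-24, 6e-23),
                         molar_mass = 18.02)
  list(methane_like = unit_absorbance_from_lines(ll_m, grid, cond),
       acetone_like = unit_absorbance_from_cross_section(xs_a, grid, cond),
       water_like = unit_absorbance_from_lines(ll_w, grid, cond))
}
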
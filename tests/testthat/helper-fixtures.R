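# Small shared fixtures: a short grid and three synthetic unit spectra
# (two dense-narrow line absorbers and one broad band), built in code.

tiny_grid <- function(n = 301) spectral_grid(2950, 2980, n)

tiny_units <- function(grid = tiny_grid(), seed = 11) {
  cond <- env_conditions()
  win <- c(grid$start - 2, grid$end + 2)
  ll1 <- synth_linelist("dense-narrow", window = win, seed = seed,
                        gas_id = "g1", n_lines_range = c(20, 40),
                        intensity_range = c(1e-22, 1.5e-21))
  xs2 <- synth_linelist("broad-band", window = win, seed = seed + 1,
                        gas_id = "g2", peak_value = 2e-5)
  ll3 <- synth_linelist("dense-narrow", window = win, seed = seed + 2,
                        gas_id = "g3", n_lines_range = c(40, 80),
                        intensity_range = c(1e-23, 6e-23), molar_mass = 18.02)
  list(unit_absorbance_from_lines(ll1, grid, cond),
       unit_absorbance_from_cross_section(xs2, grid, cond),
       unit_absorbance_from_lines(ll3, grid, cond))
}

# Brute-force Voigt reference: numerical convolution of a Lorentzian with a
# Gaussian, independent of the production evaluation path.
voigt_by_convolution <- function(x, lorentz_hwhm, doppler_hwhm) {
  sigma <- doppler_hwhm / sqrt(2 * log(2))
  vapply(x, function(xi) {
    stats::integrate(function(t) {
      lorentz_hwhm / (pi * ((xi - t)^2 + lorentz_hwhm^2)) *
        stats::dnorm(t, 0, sigma)
    }, lower = -Inf, upper = Inf, rel.tol = 1e-10)$value
  }, numeric(1))
}
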
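# Physical constants (SI)
.kB <- 1.380649e-23      # Boltzmann constant, J/K
.c_light <- 299792458    # speed of light, m/s
.amu <- 1.66053906660e-27 # atomic mass unit, kg
.atm_Pa <- 101325        # 1 atm in Pa

#' Uniform wavenumber grid
#'
#' Builds the uniform spectral axis shared by every stage of the pipeline.
#' Endpoints are inclusive, so the spacing is `(end - start) / (n_points - 1)`.
#' The default analysis window is 2950--3150 cm^-1 sampled at 3321 points
#' (spacing 200/3320 cm^-1), which resolves 1-atm rovibrational features of
#' methane and water vapour while spanning the acetone C-H stretch band.
#'
#' @param start,end window edges in cm^-1, `end > start`.
#' @param n_points number of samples, at least 2.
#' @return An object of class `spectral_grid` with elements `start`, `end`,
#'   `n_points`, `spacing` and the axis `nu` (cm^-1, strictly increasing).
#' @examples
#' g <- spectral_grid(2950, 3150, 3321)
#' g$spacing # 200/3320
#' @export
spectral_grid <- function(start, end, n_points) {
  stopifnot(is.numeric(start), is.numeric(end), is.numeric(n_points))
  if (!(end > start)) {
    stop("invalid spectral_grid: 'end' must exceed 'start' (got ",
         start, " .. ", end, ")")
  }
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L) {
    stop("invalid spectral_grid: 'n_points' must be an integer >= 2")
  }
  structure(
    list(start = as.numeric(start), end = as.numeric(end),
         n_points = n_points,
         spacing = (end - start) / (n_points - 1),
         nu = seq(start, end, length.out = n_points)),
    class = "spectral_grid")
}

#' @export
print.spectral_grid <- function(x, ...) {
  cat(sprintf("<spectral_grid> %.6g .. %.6g cm^-1, %d points (spacing %.6g cm^-1)\n",
              x$start, x$end, x$n_points, x$spacing))
  invisible(x)
}

#' Default pipeline grid (2950--3150 cm^-1, 3321 points)
#' @return a [spectral_grid()].
#' @export
default_grid <- function() spectral_grid(2950, 3150, 3321)

#' Wavenumber axis of a grid
#' @param grid a [spectral_grid()].
#' @return numeric vector of wavenumbers (cm^-1).
#' @export
wavenumbers <- function(grid) {
  stopifnot(inherits(grid, "spectral_grid"))
  grid$nu
}

#' Environmental conditions of the absorption path
#'
#' Pressure, temperature and effective optical path length under which unit
#' absorbance spectra are computed. Defaults are the multi-pass-cell operating
#' point: 1 atm, 296 K, 580 m.
#'
#' @param pressure total pressure in atm.
#' @param temperature gas temperature in K.
#' @param path_length effective optical path length in m.
#' @return An object of class `env_conditions`.
#' @export
env_conditions <- function(pressure = 1, temperature = 296, path_length = 580) {
  vals <- c(pressure = pressure, temperature = temperature,
            path_length = path_length)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("env_conditions: pressure, temperature and path_length must all be finite and > 0")
  }
  structure(list(pressure = pressure, temperature = temperature,
                 path_length = path_length),
            class = "env_conditions")
}

#' @export
print.env_conditions <- function(x, ...) {
  cat(sprintf("<env_conditions> P = %g atm, T = %g K, L = %g m\n",
              x$pressure, x$temperature, x$path_length))
  invisible(x)
}

# Ideal-gas number density in molecules / cm^3
number_density <- function(cond) {
  cond$pressure * .atm_Pa / (.kB * cond$temperature) / 1e6
}
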
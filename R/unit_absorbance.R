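#' Per-gas unit absorbance spectrum
#'
#' Absorbance of 1 ppm of a gas on a shared grid under stated conditions.
#' Mixture spectra are linear combinations of unit spectra (Beer-Lambert),
#' so a unit spectrum is the per-gas scaling basis of the whole simulator.
#'
#' @param gas_id identifier string.
#' @param grid the shared [spectral_grid()].
#' @param values absorbance (natural log) per ppm, length `grid$n_points`,
#'   all `>= 0`.
#' @return An object of class `unit_absorbance`.
#' @export
unit_absorbance <- function(gas_id, grid, values) {
  stopifnot(inherits(grid, "spectral_grid"),
            length(values) == grid$n_points)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("unit_absorbance: values must be finite and >= 0")
  }
  structure(list(gas_id = as.character(gas_id), grid = grid,
                 values = as.numeric(values)),
            class = "unit_absorbance")
}

#' @export
print.unit_absorbance <- function(x, ...) {
  cat(sprintf("<unit_absorbance> %s on %d points, peak %.4g /ppm\n",
              x$gas_id, x$grid$n_points, max(x$values)))
  invisible(x)
}

#' Line-by-line unit absorbance
#'
#' Evaluates the Beer-Lambert absorbance of 1 ppm of a gas on the grid by
#' summing Voigt profiles over all lines. For each line the profile is
#' centred at the pressure-shifted position, with Lorentz HWHM
#' `air_hwhm * P * (296/T)^temp_exponent` (trace regime: self broadening
#' neglected) and thermal Doppler HWHM from the temperature and molar mass,
#' scaled by the reference-temperature line intensity and the molecular
#' column `n(P,T) * 1e-6 * L` (ideal-gas number density in cm^-3 times the
#' 1 ppm mixing ratio times the path in cm). Conditions at the HITRAN
#' reference temperature 296 K are assumed for the intensity; the data model
#' retains the lower-state energy for future temperature scaling.
#'
#' @param linelist a [line_list()].
#' @param grid a [spectral_grid()].
#' @param cond an [env_conditions()].
#' @param wing_cutoff evaluate each line only within this distance of its
#'   centre, cm^-1 (line-by-line convention; `Inf` disables truncation).
#' @return a [unit_absorbance()] (absorbance per ppm, natural log).
#' @export
unit_absorbance_from_lines <- function(linelist, grid, cond,
                                       wing_cutoff = 25) {
  stopifnot(inherits(linelist, "line_list"), inherits(grid, "spectral_grid"),
            inherits(cond, "env_conditions"))
  nu <- grid$nu
  alpha <- numeric(grid$n_points)
  ln <- linelist$lines
  if (!nrow(ln)) {
    warning("unit_absorbance_from_lines: empty line list for ",
            linelist$gas_id, "; returning zero spectrum")
    return(unit_absorbance(linelist$gas_id, grid, alpha))
  }
  column <- number_density(cond) * 1e-6 * (cond$path_length * 100) # cm^-2 per ppm
  t_ratio <- 296 / cond$temperature
  for (r in seq_len(nrow(ln))) {
    center <- ln$center[r] + ln$pressure_shift[r] * cond$pressure
    gl <- ln$air_hwhm[r] * cond$pressure * t_ratio^ln$temp_exponent[r]
    gd <- doppler_hwhm(ln$center[r], cond$temperature, linelist$molar_mass)
    idx <- if (is.finite(wing_cutoff)) {
      which(abs(nu - center) <= wing_cutoff)
    } else {
      seq_along(nu)
    }
    if (!length(idx)) next
    phi <- voigt_profile(nu[idx] - center, gl, gd)
    alpha[idx] <- alpha[idx] + ln$intensity[r] * column * phi
  }
  unit_absorbance(linelist$gas_id, grid, alpha)
}

#' Unit absorbance from a composite cross-section table
#'
#' Interpolates a PNNL-style table (absorbance per ppm m, conventionally
#' base 10) linearly onto the grid, multiplies by the path length in metres
#' and converts to natural-log absorbance. The table must span the grid:
#' extrapolation is refused. Negative table values (measurement baseline
#' artifacts) are clipped to zero, with the clipped count reported as a
#' message and recorded in the `clipped` attribute.
#'
#' @param table a [cross_section_table()].
#' @param grid a [spectral_grid()].
#' @param cond an [env_conditions()]; only the path length is used.
#' @param xsec_log_base base of the table's absorbance values, 10 (PNNL
#'   convention, converted by ln 10) or `exp(1)` for tables already natural.
#' @return a [unit_absorbance()] with attribute `clipped` (number of clipped
#'   negative nodes).
#' @export
unit_absorbance_from_cross_section <- function(table, grid, cond,
                                               xsec_log_base = 10) {
  stopifnot(inherits(table, "cross_section_table"),
            inherits(grid, "spectral_grid"), inherits(cond, "env_conditions"))
  lo <- min(table$wavenumbers); hi <- max(table$wavenumbers)
  if (grid$start < lo || grid$end > hi) {
    stop(sprintf(paste0("unit_absorbance_from_cross_section: grid %.6g..%.6g ",
                        "cm^-1 not covered by table %.6g..%.6g cm^-1 ",
                        "(uncovered: %s)"),
                 grid$start, grid$end, lo, hi,
                 paste(c(if (grid$start < lo) sprintf("%.6g..%.6g", grid$start, lo),
                         if (grid$end > hi) sprintf("%.6g..%.6g", hi, grid$end)),
                       collapse = " and ")))
  }
  vals <- table$values
  n_neg <- sum(vals < 0)
  if (n_neg > 0) {
    message("unit_absorbance_from_cross_section: clipped ", n_neg,
            " negative cross-section value(s) to 0")
    vals <- pmax(vals, 0)
  }
  y <- stats::approx(table$wavenumbers, vals, xout = grid$nu)$y
  y <- y * cond$path_length * log(xsec_log_base)
  out <- unit_absorbance(table$gas_id, grid, y)
  attr(out, "clipped") <- n_neg
  out
}

#' Blend unit spectra into a mixture spectrum
#'
#' Beer-Lambert mixture absorbance: the concentration-weighted sum of the
#' unit spectra plus an optional additive noise vector.
#'
#' @param units list of [unit_absorbance()] objects sharing one grid.
#' @param concentrations ppm per gas, `>= 0`, one per unit spectrum.
#' @param noise optional additive vector of grid length (sensor noise term),
#'   or `NULL` for a noise-free blend.
#' @return numeric absorbance vector of grid length.
#' @examples
#' g <- spectral_grid(0, 1, 5)
#' u <- unit_absorbance("a", g, rep(0.01, 5))
#' blend(list(u), 10)
#' @export
blend <- function(units, concentrations, noise = NULL) {
  stopifnot(is.list(units), length(units) == length(concentrations))
  if (any(concentrations < 0)) stop("blend: concentrations must be >= 0")
  if (!length(units)) stop("blend: need at least one unit spectrum")
  g0 <- units[[1]]$grid
  for (u in units) {
    stopifnot(inherits(u, "unit_absorbance"))
    if (u$grid$n_points != g0$n_points ||
        u$grid$start != g0$start || u$grid$end != g0$end) {
      stop("blend: unit spectra must share one grid (mismatch at gas ",
           u$gas_id, ")")
    }
  }
  U <- vapply(units, function(u) u$values, numeric(g0$n_points))
  s <- drop(U %*% concentrations)
  if (!is.null(noise)) {
    stopifnot(length(noise) == g0$n_points)
    s <- s + noise
  }
  s
}
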
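# Humlicek (1982) four-region rational approximation of the complex
# probability function w(z), z = x + iy, y >= 0. Returns Re(w), i.e. the
# Voigt function K(x, y). Vectorised over x for scalar y. Relative accuracy
# of Re(w) better than 1e-4 over the whole upper half plane, which is the
# accepted standard for line-by-line atmospheric codes.
humlicek_w4 <- function(x, y) {
  t <- complex(real = y, imaginary = -x)
  s <- abs(x) + y
  w <- complex(length(x))

  r1 <- s >= 15
  if (any(r1)) {
    tt <- t[r1]
    w[r1] <- tt * 0.5641896 / (0.5 + tt * tt)
  }
  r2 <- !r1 & s >= 5.5
  if (any(r2)) {
    tt <- t[r2]
    u <- tt * tt
    w[r2] <- tt * (1.410474 + u * 0.5641896) / (0.75 + u * (3.0 + u))
  }
  r3 <- !r1 & !r2 & (y >= 0.195 * abs(x) - 0.176)
  if (any(r3)) {
    tt <- t[r3]
    w[r3] <- (16.4955 + tt * (20.20933 + tt * (11.96482 +
               tt * (3.778987 + tt * 0.5642236)))) /
             (16.4955 + tt * (38.82363 + tt * (39.27121 +
               tt * (21.69274 + tt * (6.699398 + tt)))))
  }
  r4 <- !r1 & !r2 & !r3
  if (any(r4)) {
    tt <- t[r4]
    u <- tt * tt
    w[r4] <- exp(u) - tt * (36183.31 - u * (3321.9905 - u * (1540.787 -
               u * (219.0313 - u * (35.76683 - u * (1.320522 - u * 0.56419)))))) /
             (32066.6 - u * (24322.84 - u * (9022.228 - u * (2186.181 -
               u * (364.2191 - u * (61.57037 - u * (1.841439 - u)))))))
  }
  Re(w)
}

#' Area-normalised Voigt line shape
#'
#' Convolution of a Lorentzian (pressure broadening) with a Gaussian (Doppler
#' broadening), parameterised by their half widths at half maximum. Degenerate
#' widths fall back to the exact Lorentzian or Gaussian. The profile
#' integrates to 1 over the real line (units 1/cm^-1).
#'
#' @param offsets distances from line centre, cm^-1 (any sign).
#' @param lorentz_hwhm Lorentzian HWHM, cm^-1, `>= 0`.
#' @param doppler_hwhm Gaussian (Doppler) HWHM, cm^-1, `>= 0`. Not both zero.
#' @return numeric vector of profile values, same length as `offsets`.
#' @examples
#' x <- seq(-1, 1, length.out = 5)
#' voigt_profile(x, lorentz_hwhm = 0.05, doppler_hwhm = 0.01)
#' @export
voigt_profile <- function(offsets, lorentz_hwhm, doppler_hwhm) {
  stopifnot(is.numeric(offsets), length(lorentz_hwhm) == 1,
            length(doppler_hwhm) == 1)
  if (lorentz_hwhm < 0 || doppler_hwhm < 0) {
    stop("voigt_profile: widths must be >= 0")
  }
  if (lorentz_hwhm == 0 && doppler_hwhm == 0) {
    stop("voigt_profile: Lorentz and Doppler widths cannot both be zero")
  }
  if (doppler_hwhm == 0) {
    g <- lorentz_hwhm
    return(g / (pi * (offsets^2 + g^2)))
  }
  sigma <- doppler_hwhm / sqrt(2 * log(2))
  if (lorentz_hwhm == 0) {
    return(exp(-offsets^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi)))
  }
  x <- offsets / (sigma * sqrt(2))
  y <- lorentz_hwhm / (sigma * sqrt(2))
  humlicek_w4(x, y) / (sigma * sqrt(2 * pi))
}

#' Doppler half width at half maximum
#'
#' Thermal Doppler HWHM of a transition at wavenumber `center` for a molecule
#' of the given molar mass.
#'
#' @param center line centre, cm^-1.
#' @param temperature gas temperature, K.
#' @param molar_mass molar mass, g/mol.
#' @return HWHM in cm^-1.
#' @export
doppler_hwhm <- function(center, temperature, molar_mass) {
  stopifnot(temperature > 0, molar_mass > 0)
  m_kg <- molar_mass * .amu
  center / .c_light * sqrt(2 * log(2) * .kB * temperature / m_kg)
}
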
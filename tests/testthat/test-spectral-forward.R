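test_that("grid construction gives an inclusive uniform axis", {
  g <- spectral_grid(2950, 3150, 3321)
  expect_equal(g$spacing, 200 / 3320, tolerance = 1e-12)
  expect_equal(length(g$nu), 3321)
  expect_equal(g$nu[1], 2950)
  expect_equal(g$nu[3321], 3150)
  expect_true(all(diff(g$nu) > 0))
  expect_equal(max(abs(diff(g$nu) - g$spacing)), 0, tolerance = 1e-9)

  g2 <- spectral_grid(0, 1, 2)
  expect_equal(g2$nu, c(0, 1))

  expect_error(spectral_grid(3150, 2950, 10), "exceed")
  expect_error(spectral_grid(0, 1, 1), "n_points")
})

test_that("voigt profile recovers its analytic limits", {
  x <- seq(-1, 1, length.out = 21)
  g <- 0.05
  expect_equal(voigt_profile(x, g, 0), g / (pi * (x^2 + g^2)),
               tolerance = 1e-6)
  d <- 0.03
  sigma <- d / sqrt(2 * log(2))
  expect_equal(voigt_profile(x, 0, d), dnorm(x, 0, sigma), tolerance = 1e-6)
  expect_error(voigt_profile(x, 0, 0), "both")
  expect_error(voigt_profile(x, -1, 1), ">= 0")
})

test_that("voigt profile is area-normalised, symmetric and non-negative", {
  # Gaussian-dominated case: the Lorentzian tail beyond the +/- 200-HWHM
  # integration range stays below the 1e-3 area tolerance
  gl <- 0.005; gd <- 0.05
  hw <- max(gl, gd)
  x <- seq(-200 * hw, 200 * hw, length.out = 400001)
  v <- voigt_profile(x, gl, gd)
  area <- sum((v[-1] + v[-length(v)]) / 2) * diff(x)[1]
  expect_gte(area, 0.999)
  expect_lte(area, 1.001)
  expect_true(all(v >= 0))
  expect_equal(v, rev(v), tolerance = 1e-12)
})

test_that("voigt profile matches a brute-force convolution reference", {
  cases <- expand.grid(x = c(0, 0.01, 0.1, 0.5, 2, 10),
                       gl = c(0.002, 0.05, 0.2),
                       gd = c(0.005, 0.05))
  for (r in seq_len(nrow(cases))) {
    got <- voigt_profile(cases$x[r], cases$gl[r], cases$gd[r])
    ref <- voigt_by_convolution(cases$x[r], cases$gl[r], cases$gd[r])
    expect_equal(got, ref, tolerance = 1e-4)
  }
})

test_that("line-by-line unit absorbance matches a term-by-term oracle", {
  grid <- spectral_grid(1000, 1001, 5)
  cond <- env_conditions(pressure = 0.8, temperature = 296, path_length = 100)
  line <- data.frame(center = 1000.4, intensity = 3e-21, air_hwhm = 0.06,
                     self_hwhm = 0.08, lower_state_energy = 100,
                     temp_exponent = 0.7, pressure_shift = -0.008)
  ll <- line_list("test", line, molar_mass = 16.04)
  ua <- unit_absorbance_from_lines(ll, grid, cond)

  # independent scalar evaluation of S * phi * (n * chi * L)
  kB <- 1.380649e-23
  n_cm3 <- cond$pressure * 101325 / (kB * cond$temperature) / 1e6
  column <- n_cm3 * 1e-6 * cond$path_length * 100
  center <- line$center + line$pressure_shift * cond$pressure
  gl <- line$air_hwhm * cond$pressure
  m_kg <- 16.04 * 1.66053906660e-27
  gd <- line$center / 299792458 *
    sqrt(2 * log(2) * kB * cond$temperature / m_kg)
  expected <- vapply(grid$nu, function(nu) {
    line$intensity * voigt_profile(nu - center, gl, gd) * column
  }, numeric(1))
  expect_equal(ua$values, expected, tolerance = 1e-10)
})

test_that("unit absorbance is linear in path length and handles empty lists", {
  grid <- tiny_grid(51)
  ll <- synth_linelist("dense-narrow", window = c(2950, 2980), seed = 3,
                       n_lines_range = c(10, 20))
  u1 <- unit_absorbance_from_lines(ll, grid, env_conditions(path_length = 290))
  u2 <- unit_absorbance_from_lines(ll, grid, env_conditions(path_length = 580))
  expect_equal(u2$values, 2 * u1$values, tolerance = 1e-12)

  empty <- line_list("none", data.frame(center = numeric(),
    intensity = numeric(), air_hwhm = numeric(), self_hwhm = numeric(),
    lower_state_energy = numeric(), temp_exponent = numeric(),
    pressure_shift = numeric()), molar_mass = 16)
  expect_warning(u0 <- unit_absorbance_from_lines(empty, grid,
                                                  env_conditions()),
                 "empty")
  expect_equal(u0$values, rep(0, grid$n_points))
})

test_that("cross-section ingest interpolates, scales by path and log base", {
  grid <- spectral_grid(2951, 2979, 15)
  tab <- cross_section_table(seq(2950, 2980, by = 0.5),
                             rep(0.001, 61), gas_id = "x")
  u <- unit_absorbance_from_cross_section(tab, grid, env_conditions())
  expect_equal(u$values, rep(0.001 * 580 * log(10), 15), tolerance = 1e-12)

  # identity interpolation at table nodes with L = 1 m
  grid2 <- spectral_grid(2950, 2980, 61)
  vals <- 1e-4 * (1 + sin(seq(0, 3, length.out = 61))^2)
  tab2 <- cross_section_table(grid2$nu, vals)
  u2 <- unit_absorbance_from_cross_section(tab2, grid2,
                                           env_conditions(path_length = 1))
  expect_equal(u2$values, vals * log(10), tolerance = 1e-12)

  # natural-log tables pass through unscaled
  u2e <- unit_absorbance_from_cross_section(tab2, grid2,
                                            env_conditions(path_length = 1),
                                            xsec_log_base = exp(1))
  expect_equal(u2e$values, vals, tolerance = 1e-12)

  expect_error(unit_absorbance_from_cross_section(tab, spectral_grid(2940, 2979, 5),
                                                  env_conditions()),
               "not covered")
})

test_that("negative cross-section values are clipped and counted", {
  vals <- c(-1e-5, rep(2e-4, 9), -2e-5)
  tab <- cross_section_table(seq(2950, 2960, length.out = 11), vals)
  grid <- spectral_grid(2950, 2960, 11)
  expect_message(u <- unit_absorbance_from_cross_section(tab, grid,
                                                         env_conditions()),
                 "clipped 2")
  expect_equal(attr(u, "clipped"), 2)
  expect_true(all(u$values >= 0))
})

test_that("blend is additive, linear and matches a scalar brute-force sum", {
  grid <- tiny_grid(41)
  units <- tiny_units(grid)
  expect_equal(blend(units, c(0, 0, 0)), rep(0, 41))

  set.seed(5)
  c1 <- runif(3, 0, 40); c2 <- runif(3, 0, 40)
  expect_equal(blend(units, c1) + blend(units, c2), blend(units, c1 + c2),
               tolerance = 1e-12)

  # brute force with scalar loops
  ref <- numeric(41)
  for (k in 1:41) {
    for (i in 1:3) ref[k] <- ref[k] + c1[i] * units[[i]]$values[k]
  }
  expect_equal(blend(units, c1), ref, tolerance = 1e-12)

  noise <- rnorm(41, 0, 0.01)
  expect_equal(blend(units, c1, noise), ref + noise, tolerance = 1e-12)

  other <- tiny_units(spectral_grid(2950, 2980, 42))
  expect_error(blend(list(units[[1]], other[[2]]), c(1, 1)), "share one grid")
  expect_error(blend(units, c(-1, 0, 0)), ">= 0")
})

test_that("HITRAN fixed-width records parse into a sorted line list", {
  # two synthetic 160-character records (CH4, molecule 6), unsorted centers
  rec <- function(mol, iso, nu, S, ga, gs, E, na, d) {
    sprintf("%2d%1d%12.6f%10.3E%10.3E%5.3f%5.3f%10.4f%4.2f%8.5f%s",
            mol, iso, nu, S, 1e-3, ga, gs, E, na, d,
            paste(rep(" ", 93), collapse = ""))
  }
  lines <- c(rec(6, 1, 3010.5, 2e-21, 0.06, 0.08, 200, 0.75, -0.007),
             rec(6, 1, 2995.2, 5e-22, 0.05, 0.07, 150, 0.70, 0.002),
             rec(1, 1, 3000.0, 1e-22, 0.04, 0.20, 300, 0.65, 0.001))
  f <- withr::local_tempfile(fileext = ".par")
  writeLines(lines, f)
  ll <- read_hitran_par(f, molecule = 6)
  expect_s3_class(ll, "line_list")
  expect_equal(nrow(ll$lines), 2)
  expect_equal(ll$lines$center, c(2995.2, 3010.5))
  expect_equal(ll$lines$intensity[2], 2e-21)
  expect_equal(ll$lines$pressure_shift[1], 0.002, tolerance = 1e-9)
  expect_equal(ll$gas_id, "CH4")
  expect_equal(ll$molar_mass, 16.0313, tolerance = 1e-4)
})
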
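test_that("class masks cover the seven composition patterns", {
  expect_equal(mixture_classes(), c("MAW", "MA", "MW", "AW", "M", "A", "W"))
  expect_equal(class_mask("MAW"), c(1L, 1L, 1L))
  expect_equal(class_mask("M"), c(1L, 0L, 0L))
  expect_equal(class_mask("A"), c(0L, 1L, 0L))
  expect_equal(class_mask("W"), c(0L, 0L, 1L))
  expect_error(class_mask("Z"), "unknown")
})

test_that("concentration draws respect class masks and ranges", {
  set.seed(42)
  lab <- sample_concentrations("M")
  expect_equal(lab$ci, c(1L, 0L, 0L))
  expect_true(lab$cr[1] >= 0 && lab$cr[1] <= 50)
  expect_equal(lab$cr[2:3], c(0, 0))

  lab_w <- sample_concentrations("W")
  expect_true(lab_w$cr[3] >= 1000 && lab_w$cr[3] <= 2000)
  expect_equal(lab_w$cr[1:2], c(0, 0))

  # distributional check against the stated uniform sampler
  set.seed(7)
  draws <- t(replicate(10000, sample_concentrations("MAW")$cr))
  expect_true(all(draws[, 1] >= 0 & draws[, 1] <= 50))
  expect_true(all(draws[, 3] >= 1000 & draws[, 3] <= 2000))
  expect_gt(ks.test(draws[, 1], "punif", 0, 50)$p.value, 0.01)
  expect_gt(ks.test(draws[, 2], "punif", 0, 50)$p.value, 0.01)
  expect_gt(ks.test(draws[, 3], "punif", 1000, 2000)$p.value, 0.01)
})

test_that("disabled perturbation channels are the identity", {
  grid <- tiny_grid(101)
  spec <- sin(seq(0, 4, length.out = 101))^2
  cfg <- perturbation_config(enable_power = FALSE, enable_unknown = FALSE,
                             enable_noise = FALSE, enable_baseline = FALSE)
  set.seed(1)
  expect_identical(apply_perturbations(spec, cfg, grid), spec)
})

test_that("white-noise channel has the folded-normal mean deviation", {
  grid <- spectral_grid(0, 1, 100000)
  spec <- rep(0.3, grid$n_points)
  s <- 0.012
  cfg <- perturbation_config(enable_power = FALSE, enable_unknown = FALSE,
                             enable_baseline = FALSE, noise_sigma = s)
  set.seed(99)
  out <- apply_perturbations(spec, cfg, grid)
  expect_equal(mean(abs(out - spec)), s * sqrt(2 / pi), tolerance = 0.02)
})

test_that("unknown-absorber bands are additive, bounded and truncated", {
  grid <- spectral_grid(2950, 3150, 2001)
  spec <- rep(0, 2001)
  cfg <- perturbation_config(enable_power = FALSE, enable_noise = FALSE,
                             enable_baseline = FALSE,
                             unknown_band_count = c(1L, 3L),
                             unknown_band_depth = c(0.02, 0.1))
  set.seed(4)
  out <- apply_perturbations(spec, cfg, grid)
  expect_true(all(out >= 0))
  expect_lte(max(out), 3 * 0.1)
  expect_gt(max(out), 0)
  # truncation at +/- 5 widths leaves exact zeros somewhere on a wide grid
  expect_gt(sum(out == 0), 0)
})

test_that("power fluctuation acts multiplicatively in transmittance", {
  grid <- tiny_grid(501)
  spec <- rep(0.5, 501)
  cfg <- perturbation_config(enable_unknown = FALSE, enable_noise = FALSE,
                             enable_baseline = FALSE,
                             power_fluct_amplitude = 0.02)
  set.seed(2)
  out <- apply_perturbations(spec, cfg, grid)
  gain <- exp(spec - out)
  expect_true(all(gain >= 0.98 - 1e-9 & gain <= 1.02 + 1e-9))
})

test_that("dataset generation is deterministic, class-exact and label-consistent", {
  grid <- tiny_grid(61)
  units <- tiny_units(grid)
  ds1 <- generate_dataset(70, grid, units, seed = 5)
  ds2 <- generate_dataset(70, grid, units, seed = 5)
  expect_identical(ds1$X, ds2$X)
  expect_identical(ds1$Y, ds2$Y)

  expect_equal(unname(table(ds1$class)[mixture_classes()]),
               rep(10L, 7L), ignore_attr = TRUE)
  # ci_i = 0 <=> cr_i = 0
  expect_true(all((ds1$Y[, 1:3] == 0) == (ds1$Y[, 4:6] == 0)))
  for (j in seq_len(nrow(ds1$Y))) {
    expect_equal(unname(ds1$Y[j, 1:3]), as.numeric(class_mask(ds1$class[j])))
  }

  ds3 <- generate_dataset(7, grid, units, class_allocation = rep(1L, 7),
                          seed = 1)
  expect_equal(nrow(unique(ds3$Y[, 1:3])), 7)

  expect_error(generate_dataset(10, grid, units,
                                class_allocation = rep(1L, 7), seed = 1),
               "summing to m")
})

test_that("auto-resolved noise sigma targets the water-band SNR", {
  grid <- tiny_grid(61)
  units <- tiny_units(grid)
  ds <- generate_dataset(14, grid, units, seed = 2)
  expect_equal(ds$cfg$noise_sigma, max(units[[3]]$values) * 1500 / 150,
               tolerance = 1e-12)
})

test_that("holdout and k-fold splits are disjoint, covering and sized", {
  sp <- split_holdout(100, 0.1, seed = 3)
  expect_equal(length(sp$test), 10)
  expect_equal(length(sp$train), 90)
  expect_equal(sort(c(sp$train, sp$test)), 1:100)

  folds <- kfold(sp$train, k = 10, seed = 3)
  expect_equal(lengths(folds), rep(9L, 10))
  expect_equal(sort(unlist(folds)), sort(sp$train))

  for (trial in 1:5) {
    m <- sample(20:200, 1); k <- sample(2:10, 1)
    f <- kfold(seq_len(m), k = k, seed = trial)
    expect_equal(sort(unlist(f)), seq_len(m))
    expect_lte(diff(range(lengths(f))), 1)
  }
  expect_error(kfold(1:5, k = 6), "k <=")
})

test_that("synthetic fixtures are deterministic and spectrally overlapping", {
  ll1 <- synth_linelist("dense-narrow", seed = 12)
  ll2 <- synth_linelist("dense-narrow", seed = 12)
  expect_identical(ll1$lines, ll2$lines)

  xs <- synth_linelist("broad-band", seed = 12)
  expect_true(all(diff(xs$wavenumbers) > 0))
  expect_true(all(xs$values >= 0))

  grid <- tiny_grid(81)
  units <- tiny_units(grid)
  # overlapping support: elementwise product of unit spectra is nonzero
  expect_gt(sum(units[[1]]$values * units[[2]]$values), 0)
  expect_gt(sum(units[[1]]$values * units[[3]]$values), 0)
})

test_that("dataset containers round-trip through HDF5 and export to CSV", {
  grid <- tiny_grid(31)
  units <- tiny_units(grid)
  ds <- generate_dataset(14, grid, units, seed = 8)
  h5 <- withr::local_tempfile(fileext = ".h5")
  write_dataset(ds, h5)
  back <- read_dataset(h5)
  expect_equal(back$X, ds$X, tolerance = 1e-12)
  expect_equal(back$Y, ds$Y, tolerance = 1e-12)
  expect_equal(back$class, ds$class)
  expect_equal(back$grid$n_points, ds$grid$n_points)
  expect_equal(back$cfg$noise_sigma, ds$cfg$noise_sigma, tolerance = 1e-9)

  pre <- withr::local_tempfile()
  paths <- write_dataset_csv(ds, pre)
  X <- as.matrix(read.csv(paste0(pre, "_X.csv"), header = FALSE))
  expect_equal(unname(X), unname(ds$X), tolerance = 1e-6)
})
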
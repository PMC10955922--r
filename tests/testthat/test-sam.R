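test_that("config constructors validate their arguments", {
  expect_s3_class(sam_config(), "sam_config")
  expect_equal(sam_config()$hidden_widths, c(196L, 74L, 211L))
  expect_error(sam_config(dropout = 1), "dropout")
  expect_error(sam_config(cr_scale = c(1, 1)), "cr_scale")
  expect_s3_class(train_config(), "train_config")
  expect_equal(train_config()$lambda_con, 100)
  expect_equal(train_config()$adam_beta1, 0.5)
  expect_error(train_config(learning_rate = 0))
})

test_that("forward pass with zero weights is the sigmoid/identity origin", {
  cfg <- sam_config(input_width = 10, hidden_widths = c(4, 3))
  st <- sam_init(cfg, seed = 1)
  for (l in seq_along(st$W)) {
    st$W[[l]] <- st$W[[l]] * 0
    st$b[[l]] <- st$b[[l]] * 0
  }
  pred <- sam_forward(st, rnorm(10))
  expect_equal(unname(pred$ci_prob), c(0.5, 0.5, 0.5))
  expect_equal(unname(pred$cr_raw), c(0, 0, 0))

  x <- rnorm(10)
  st2 <- sam_init(cfg, seed = 2)
  p1 <- sam_forward(st2, x)
  p2 <- sam_forward(st2, x)
  expect_identical(p1, p2)
  expect_error(sam_forward(st2, rnorm(9)), "length")
})

test_that("forward pass matches a hand-computed affine chain", {
  cfg <- sam_config(input_width = 2, hidden_widths = 1, dropout = 0,
                    cr_scale = c(1, 1, 1))
  st <- sam_init(cfg, seed = 1)
  st$W[[1]] <- matrix(c(0.3, -0.2), nrow = 2)
  st$b[[1]] <- 0.1
  st$W[[2]] <- matrix(seq(0.1, 0.6, by = 0.1), nrow = 1)
  st$b[[2]] <- rep(-0.05, 6)
  x <- c(2, 1)
  a1 <- max(0.3 * 2 - 0.2 * 1 + 0.1, 0)        # 0.5
  z_out <- a1 * seq(0.1, 0.6, by = 0.1) - 0.05
  pred <- sam_forward(st, x)
  expect_equal(unname(pred$ci_prob), 1 / (1 + exp(-z_out[1:3])),
               tolerance = 1e-12)
  expect_equal(unname(pred$cr_raw), z_out[4:6], tolerance = 1e-12)
})

test_that("loss components take their closed-form values", {
  m <- 8
  p_half <- matrix(0.5, m, 3)
  g <- matrix(rbinom(m * 3, 1, 0.4), m)
  cr <- matrix(runif(m * 3), m)
  ls <- sam_loss(p_half, cr, g, cr, lambda_con = 100)
  expect_equal(ls$iden, log(2), tolerance = 1e-12)
  expect_equal(ls$con, 0)
  expect_equal(ls$obj, ls$iden)

  # lambda linearity
  cr2 <- cr + 0.3
  l1 <- sam_loss(p_half, cr2, g, cr, lambda_con = 50)
  l2 <- sam_loss(p_half, cr2, g, cr, lambda_con = 100)
  expect_equal(l2$obj - l2$iden, 2 * (l1$obj - l1$iden), tolerance = 1e-12)
  expect_gte(l1$iden, 0)
  expect_gte(l1$con, 0)

  expect_error(sam_loss(matrix(NaN, 1, 3), matrix(0, 1, 3),
                        matrix(1, 1, 3), matrix(0, 1, 3)), "non-finite")
})

test_that("training converges on a small separable task", {
  grid <- tiny_grid(121)
  units <- tiny_units(grid)
  ds <- generate_dataset(200, grid, units, seed = 21)
  cfg <- sam_config(input_width = 121, hidden_widths = c(32, 16, 24))
  tc <- train_config(batch_size = 32, epochs = 50, learning_rate = 0.002,
                     lr_schedule = "cosine_tail", init = "spectral",
                     seed = 9)
  st <- sam_train(ds$X, ds$Y, cfg, tc)
  expect_equal(nrow(st$history), 50)
  expect_lt(st$history$obj[50], 0.1 * st$history$obj[1])
})

test_that("training is reproducible and epochs = 0 returns untrained state", {
  grid <- tiny_grid(41)
  units <- tiny_units(grid)
  ds <- generate_dataset(40, grid, units, seed = 3)
  cfg <- sam_config(input_width = 41, hidden_widths = c(8, 6))
  tc <- train_config(batch_size = 16, epochs = 3, learning_rate = 0.002,
                     seed = 4)
  st1 <- sam_train(ds$X, ds$Y, cfg, tc)
  st2 <- sam_train(ds$X, ds$Y, cfg, tc)
  expect_identical(st1$history, st2$history)
  expect_identical(st1$W, st2$W)

  st0 <- sam_train(ds$X, ds$Y, cfg, train_config(epochs = 0, seed = 4))
  expect_equal(nrow(st0$history), 0)
})

test_that("gating zeroes sub-threshold concentrations and is idempotent", {
  gate <- gasblendr:::gate_concentrations
  expect_equal(gate(c(0.4, 0.9, 0.6), c(3.2, 7.7, 1200)), c(0, 7.7, 1200))
  # exactly 0.5 gates to absent (strict inequality)
  expect_equal(gate(c(0.5, 0.5, 0.5), c(1, 2, 3)), c(0, 0, 0))
  expect_equal(gate(c(0.1, 0.2, 0.3), c(5, 5, 5)), c(0, 0, 0))
  # negative raw concentrations are clipped when passed
  expect_equal(gate(c(0.9, 0.9, 0.9), c(-2, 1, 3)), c(0, 1, 3))
  # idempotence: regating the gated output is a fixed point
  g1 <- gate(c(0.4, 0.9, 0.6), c(3.2, 7.7, 1200))
  expect_equal(gate(c(0.4, 0.9, 0.6), g1), g1)
})

test_that("predict_gated applies the gating rule end to end", {
  cfg <- sam_config(input_width = 5, hidden_widths = 2, cr_scale = c(1, 1, 1))
  st <- sam_init(cfg, seed = 6)
  x <- rnorm(5)
  pred <- predict_gated(st, x)
  expect_equal(unname(pred$cr_gated),
               unname(ifelse(pred$ci_prob > 0.5, pmax(pred$cr_raw, 0), 0)))
})

test_that("checkpoints round-trip bit-exactly and reject unknown versions", {
  cfg <- sam_config(input_width = 12, hidden_widths = c(5, 4))
  st <- sam_init(cfg, seed = 11)
  f <- withr::local_tempfile(fileext = ".rds")
  sam_save(st, f)
  back <- sam_load(f)
  expect_identical(back$W, st$W)
  expect_identical(back$b, st$b)
  expect_identical(back$cfg, st$cfg)

  bad <- readRDS(f)
  bad$format_version <- "2.0"
  saveRDS(bad, f)
  expect_error(sam_load(f), "format_version")
})
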
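test_that("adversarial loss matches its closed forms and brute force", {
  d1 <- array(1, c(4, 4)); d0 <- array(0, c(4, 4))
  expect_equal(adversarial_loss(d1, d0), 0)
  dh <- array(0.5, c(4, 4))
  expect_equal(adversarial_loss(dh, dh), 0.5)
  withr::with_seed(31, {
    a <- array(stats::runif(16), c(4, 4))
    b <- array(stats::runif(16), c(4, 4))
  })
  brute <- sum((1 - a)^2) / 16 + sum(b^2) / 16
  expect_lt(abs(adversarial_loss(a, b) - brute), 1e-10)
  expect_error(adversarial_loss(a * 2, b), "\\[0, 1\\]")
  expect_error(adversarial_loss(a, array(0.5, c(2, 2))), "shape")
})

test_that("cycle loss is the mean absolute difference", {
  x <- array(0.2, c(8, 8))
  expect_equal(cycle_loss(x, x), 0)
  expect_equal(cycle_loss(x, array(-0.3, c(8, 8))), 0.5)
  withr::with_seed(32, {
    a <- array(stats::rnorm(64), c(8, 8))
    b <- array(stats::rnorm(64), c(8, 8))
  })
  expect_lt(abs(cycle_loss(a, b) - sum(abs(a - b)) / 64), 1e-10)
  expect_error(cycle_loss(a, array(0, c(4, 4))), "shape")
})

test_that("the full objective combines terms linearly in lambda", {
  expect_equal(total_loss(0.5, 0.3, 0.1, 0.2, 10), 3.8)
  expect_equal(total_loss(0, 0, 0, 0, 10), 0)
  expect_equal(total_loss(0.5, 0.3, 0.1, 0.2, 0), 0.8)
  lams <- c(0, 1, 2.5, 10)
  vals <- vapply(lams, function(l) total_loss(0.4, 0.2, 0.3, 0.5, l),
                 numeric(1))
  expect_equal(diff(vals) / diff(lams), rep(0.8, 3))
  expect_error(total_loss(-0.1, 0, 0, 0, 10), "nonnegative")
})

test_that("learning rate plateaus then decays linearly to zero", {
  cfg <- model_config()
  expect_equal(lr_schedule(0, cfg), 2e-4)
  expect_equal(lr_schedule(19, cfg), 2e-4)
  expect_equal(lr_schedule(60, cfg), 2e-4 * (100 - 60) / 80)
  expect_equal(lr_schedule(60, cfg), 1e-4)
  expect_equal(lr_schedule(99, cfg), 2e-4 * 1 / 80)
  expect_error(lr_schedule(100, cfg), "range")
  expect_error(lr_schedule(-1, cfg), "range")
})

test_that("model config validates its fields", {
  expect_equal(model_config()$resnet_blocks, 9L)
  expect_equal(model_config()$lambda_cyc, 10)
  expect_equal(model_config()$batch_size, 2L)
  expect_equal(model_config()$beta1, 0.5)
  expect_equal(model_config()$beta2, 0.5)
  expect_error(model_config(image_size = 130), "divisible")
  expect_error(model_config(lr_initial = 0), "lr_initial")
  expect_error(model_config(lr_decay_start_epoch = 100), "epochs")
})

test_that("built models have the requested depth, bounds and determinism", {
  cfg <- model_config(scaled_profile = TRUE, seed = 77)
  mods <- build_models(cfg)
  expect_equal(n_resblocks(mods$generators$g_rct), 3)
  full <- build_models(model_config(seed = 1, base_channels = 4L,
                                    image_size = 64L))
  expect_equal(n_resblocks(full$generators$g_rct), 9)

  x <- withr::with_seed(5, array(stats::runif(64 * 64, -1, 1),
                                 c(64, 64, 1, 1)))
  y <- cyclesct:::net_predict(mods$generators$g_rct, x)
  expect_true(all(y >= -1 & y <= 1))
  d <- cyclesct:::net_predict(mods$discriminators$d_rct, x)
  expect_true(all(d >= 0 & d <= 1))

  mods2 <- build_models(cfg)
  expect_identical(mods$generators$g_rct$layers[[1]]$W,
                   mods2$generators$g_rct$layers[[1]]$W)
  expect_identical(mods$discriminators$d_cbct$layers[[3]]$W,
                   mods2$discriminators$d_cbct$layers[[3]]$W)
})

test_that("layer backward passes match finite differences", {
  set.seed(42)
  net <- structure(list(layers = list(
    cyclesct:::layer_conv(3, 1, 2, 2, 1, "zero"),
    cyclesct:::layer_inorm(2),
    cyclesct:::layer_act("relu"),
    cyclesct:::layer_resblock(2),
    cyclesct:::layer_upconv(3, 2, 1),
    cyclesct:::layer_act("tanh"))), class = "cg_net")
  x <- array(stats::rnorm(8 * 8 * 2), c(8, 8, 1, 2))
  tgt <- array(stats::rnorm(8 * 8 * 2), c(8, 8, 1, 2))
  loss_of <- function(n) mean((cyclesct:::net_forward(n, x)$out - tgt)^2)
  f <- cyclesct:::net_forward(net, x)
  dy <- array(2 * (f$out - tgt) / length(tgt), dim = dim(f$out))
  bk <- cyclesct:::net_backward(net, f$tape, dy)
  eps <- 1e-5
  cases <- list(list(1, "W", 3), list(1, "b", 1), list(2, "gamma", 2),
                list(2, "beta", 1), list(5, "W", 7))
  for (cs in cases) {
    n2 <- net
    n2$layers[[cs[[1]]]][[cs[[2]]]][cs[[3]]] <-
      n2$layers[[cs[[1]]]][[cs[[2]]]][cs[[3]]] + eps
    l1 <- loss_of(n2)
    n2$layers[[cs[[1]]]][[cs[[2]]]][cs[[3]]] <-
      n2$layers[[cs[[1]]]][[cs[[2]]]][cs[[3]]] - 2 * eps
    l0 <- loss_of(n2)
    expect_equal(bk$grads[[cs[[1]]]][[cs[[2]]]][cs[[3]]],
                 (l1 - l0) / (2 * eps), tolerance = 1e-4)
  }
  # resblock inner conv and the input gradient
  n2 <- net
  n2$layers[[4]]$layers[[1]]$W[5] <- n2$layers[[4]]$layers[[1]]$W[5] + eps
  l1 <- loss_of(n2)
  n2$layers[[4]]$layers[[1]]$W[5] <- n2$layers[[4]]$layers[[1]]$W[5] - 2 * eps
  l0 <- loss_of(n2)
  expect_equal(bk$grads[[4]][[1]]$W[5], (l1 - l0) / (2 * eps),
               tolerance = 1e-4)
  x2 <- x; x2[13] <- x2[13] + eps
  l1 <- mean((cyclesct:::net_forward(net, x2)$out - tgt)^2)
  x2[13] <- x2[13] - 2 * eps
  l0 <- mean((cyclesct:::net_forward(net, x2)$out - tgt)^2)
  expect_equal(bk$dx[13], (l1 - l0) / (2 * eps), tolerance = 1e-4)
})

test_that("gated generators start as the identity and stay bounded", {
  cfg <- model_config(scaled_profile = TRUE, seed = 9)
  mods <- build_models(cfg)
  x <- withr::with_seed(6, array(stats::runif(64 * 64, -1, 1),
                                 c(64, 64, 1, 1)))
  y <- cyclesct:::net_predict(mods$generators$g_rct, x)
  expect_identical(as.numeric(y), as.numeric(x))
})

test_that("training bookkeeping: null run, history length, determinism", {
  cfg0 <- model_config(scaled_profile = TRUE, image_size = 32L,
                       resnet_blocks = 2L, base_channels = 6L, epochs = 0L,
                       lr_decay_start_epoch = -1L, seed = 4)
  slices <- withr::with_seed(8, array(stats::runif(32 * 32 * 4, -1, 1),
                                      c(32, 32, 4)))
  fit0 <- train_cyclegan(slices, slices, cfg0)
  expect_equal(nrow(fit0$history), 0)
  expect_identical(fit0$models$generators$g_rct$layers[[1]]$W,
                   build_models(cfg0)$generators$g_rct$layers[[1]]$W)

  cfg <- model_config(scaled_profile = TRUE, image_size = 32L,
                      resnet_blocks = 2L, base_channels = 6L, epochs = 3L,
                      lr_decay_start_epoch = 1L, seed = 4)
  ct <- withr::with_seed(9, array(stats::runif(32 * 32 * 6, -1, 1),
                                  c(32, 32, 6)))
  cb <- withr::with_seed(10, array(stats::runif(32 * 32 * 6, -1, 1),
                                   c(32, 32, 6)))
  fit <- train_cyclegan(ct, cb, cfg)
  expect_equal(nrow(fit$history), 3 * (6 %/% 2))
  expect_true(all(fit$history$l_total >= 0))
  expect_equal(fit$history$l_total,
               with(fit$history, l_ct + l_cbct + 10 * (l_fw + l_bw)))
  fit2 <- train_cyclegan(ct, cb, cfg)
  expect_identical(fit$history, fit2$history)
  expect_error(train_cyclegan(ct, array(0.5, c(32, 32, 0)), cfg), "empty")
})

test_that("short training reduces the forward cycle loss across seeds", {
  finals <- initials <- numeric(3)
  for (s in 1:3) {
    cfg <- model_config(scaled_profile = TRUE, image_size = 32L,
                        resnet_blocks = 2L, base_channels = 6L, epochs = 3L,
                        lr_decay_start_epoch = 1L, seed = s)
    ph <- generate_head_phantom(random_head_spec(s, grid_shape = c(12, 32, 32),
                                                 spacing_mm = c(6, 6, 6)))
    m <- phantom_body_mask(ph)
    cbct <- degrade_to_cbct(ph, cohort_degradation(seed = s), m)
    ct_sl <- extract_slices(ph, m, n_slices = 10, size = 32)
    cb_sl <- extract_slices(cbct, m, n_slices = 10, size = 32)
    fit <- train_cyclegan(ct_sl, cb_sl, cfg)
    ep <- fit$history$epoch
    initials[s] <- median(fit$history$l_fw[ep == 0])
    finals[s] <- median(fit$history$l_fw[ep == max(ep)])
  }
  expect_lt(median(finals), median(initials))
})

test_that("volume translation honours identity and constant generators", {
  ph <- generate_head_phantom(phantom_spec(c(8, 64, 64)))
  m <- phantom_body_mask(ph)
  flat <- clip_and_flatten(ph, m)

  idg <- build_models(model_config(scaled_profile = TRUE, seed = 2))$generators$g_rct
  out <- translate_volume(flat, idg, m, image_size = 64)
  expect_lt(max(abs(out$sct$values - flat$values)), 0.5)
  expect_identical(dim(out$sct$values), dim(flat$values))

  # constant generator: always 0 in normalized units -> 500 HU inside mask
  constg <- structure(list(layers = list(
    cyclesct:::layer_conv(1, 1, 1, 1, 0, "zero", init_sd = 0)),
    kind = "generator"), class = "cg_net")
  out2 <- translate_volume(flat, constg, m, image_size = 64)
  expect_true(all(out2$sct$values[m$values] == 500))
  expect_true(all(out2$sct$values[!m$values] == -1000))
})

test_that("checkpoints restore weights and history", {
  cfg <- model_config(scaled_profile = TRUE, image_size = 32L,
                      resnet_blocks = 2L, base_channels = 6L, epochs = 1L,
                      lr_decay_start_epoch = 0L, seed = 3)
  sl <- withr::with_seed(11, array(stats::runif(32 * 32 * 4, -1, 1),
                                   c(32, 32, 4)))
  fit <- train_cyclegan(sl, sl, cfg)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(fit, cfg, f)
  ck <- load_checkpoint(f)
  expect_identical(ck$models$generators$g_rct$layers[[1]]$W,
                   fit$models$generators$g_rct$layers[[1]]$W)
  expect_equal(ck$config$lambda_cyc, cfg$lambda_cyc)
  h <- utils::read.csv(sub("\\.rds$", "_history.csv", f))
  expect_equal(nrow(h), nrow(fit$history))
})
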
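test_that("shape contract and seeded-initialization determinism", {
  net <- build_reference_unet(16L, base_channels = 8L, seed = 4L)
  xt <- matrix(rnorm(256), 16, 16)
  y <- matrix(rnorm(256), 16, 16)
  out <- predict_noise(net, xt, y, 3L)
  expect_identical(dim(out), dim(xt))
  net2 <- build_reference_unet(16L, base_channels = 8L, seed = 4L)
  expect_identical(model_fingerprint(net), model_fingerprint(net2))
  expect_identical(net$params, net2$params)
  net3 <- build_reference_unet(16L, base_channels = 8L, seed = 5L)
  expect_false(identical(model_fingerprint(net), model_fingerprint(net3)))
  expect_gt(n_params(net), 1000L)
  expect_error(build_reference_unet(15L), "divisible")
})

test_that("prediction is pure and batching equals stacked per-example results", {
  net <- build_reference_unet(8L, base_channels = 8L, seed = 1L)
  set.seed(8)
  xb <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  yb <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  xb_copy <- xb
  tt <- c(2L, 5L, 9L)
  ob <- predict_noise(net, xb, yb, tt)
  expect_identical(xb, xb_copy)  # inputs not mutated
  for (i in 1:3) {
    oi <- predict_noise(net, xb[, , i], yb[, , i], tt[i])
    expect_equal(ob[, , i], oi, tolerance = 1e-10)
  }
})

test_that("analytic gradients match finite differences", {
  # spot-check two parameters in every leaf tensor of a small network
  net <- build_reference_unet(8L, base_channels = 8L,
                              channel_mults = c(1, 2), num_groups = 4L,
                              seed = 3L)
  set.seed(42)
  N <- 2L
  xt <- matrix(rnorm(64 * N), 64, N)
  y <- matrix(rnorm(64 * N), 64, N)
  tt <- c(3, 7)
  target <- rnorm(64 * N)
  lossf <- function(params) {
    fw <- cddpm:::unet_fwd(params, net$arch, matrix(as.vector(xt), ncol = 1),
                           matrix(as.vector(y), ncol = 1), tt, N)
    sum((fw$out - target)^2)
  }
  fw <- cddpm:::unet_fwd(net$params, net$arch, matrix(as.vector(xt), ncol = 1),
                         matrix(as.vector(y), ncol = 1), tt, N)
  gr <- cddpm:::unet_bwd(net$params, net$arch, fw,
                         matrix(2 * (fw$out - target), ncol = 1))
  flg <- cddpm:::flatten_params(gr)
  set.seed(1)
  for (key in names(flg)) {
    leaf <- cddpm:::get_param_leaf(net$params, key)
    for (j in sample(length(leaf), min(2, length(leaf)))) {
      e <- 1e-5
      p1 <- leaf; p1[j] <- p1[j] + e
      p2 <- leaf; p2[j] <- p2[j] - e
      fd <- (lossf(cddpm:::set_param_leaf(net$params, key, p1)) -
             lossf(cddpm:::set_param_leaf(net$params, key, p2))) / (2 * e)
      an <- flg[[key]][j]
      expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), 1e-4)
    }
  }
})

test_that("a few hundred steps overfit a single fixed training tuple", {
  s <- linear_beta_schedule(200L, 1e-4, 0.02)
  set.seed(12)
  x0 <- tiny_phantoms(1, size = 16)[[1]]$image
  y <- x0
  eps <- matrix(rnorm(256), 16, 16)
  t_fix <- 50L
  net <- build_reference_unet(16L, base_channels = 8L, seed = 2L)
  # single-tuple gradient descent on the simplified objective
  params <- net$params
  ad <- cddpm:::adam_init(params)
  xt <- q_sample(x0, t_fix, eps, s)
  for (i in 1:500) {
    fw <- cddpm:::unet_fwd(params, net$arch, matrix(as.vector(xt), ncol = 1),
                           matrix(as.vector(y), ncol = 1), t_fix, 1L)
    resid <- fw$out - as.vector(eps)
    gr <- cddpm:::unet_bwd(params, net$arch, fw,
                           matrix(2 * resid / length(resid), ncol = 1))
    st <- cddpm:::adam_step(params, gr, ad, 2e-3)
    params <- st$params
    ad <- st$state
  }
  net$params <- params
  expect_lt(simple_loss(net, x0, y, t_fix, eps, s), 0.01)
})

test_that("training decreases the loss, is seed-reproducible, and beats the zero predictor", {
  spec <- phantom_spec(image_size = 16L, n_images = 40L, seed = 31L)
  ds <- make_task_dataset(spec, "DENOISE")
  cfg <- toy_train_config(iterations = 200L, seed = 9L)
  s <- linear_beta_schedule(cfg$T_steps, cfg$beta_start, cfg$beta_end)
  net <- build_reference_unet(16L, base_channels = 8L, seed = cfg$seed)
  tr <- train_diffusion(net, ds$train, cfg, s)
  expect_length(tr$history, 200L)
  expect_lt(mean(tail(tr$history, 50)), mean(head(tr$history, 50)))
  # bit-identical reproducibility from the same seed
  tr2 <- train_diffusion(net, ds$train, cfg, s)
  expect_identical(tr$history, tr2$history)
  # held-out comparison against the zero predictor
  set.seed(100)
  val_loss <- function(model) {
    mean(vapply(ds$val, function(p) {
      e <- matrix(rnorm(256), 16, 16)
      simple_loss(model, p$x0, p$y, sample.int(s$T, 1), e, s)
    }, numeric(1)))
  }
  set.seed(100); lt <- val_loss(tr$model)
  set.seed(100); lz <- val_loss(zero_predictor())
  expect_lt(lt, lz)
  expect_error(train_diffusion(net, list(), cfg, s), "empty")
})

test_that("checkpoint round-trip is bit-identical and schedule-checked", {
  net <- build_reference_unet(8L, base_channels = 8L, seed = 6L)
  s <- linear_beta_schedule(20L, 1e-3, 0.1)
  cfg <- toy_train_config(iterations = 10L)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(net, f, cfg, s)
  ck <- load_checkpoint(f)
  xt <- matrix(rnorm(64), 8, 8)
  y <- matrix(rnorm(64), 8, 8)
  expect_identical(predict_noise(net, xt, y, 3L),
                   predict_noise(ck$model, xt, y, 3L))
  expect_silent(cddpm:::check_schedule_match(ck$schedule_fingerprint, s))
  s2 <- linear_beta_schedule(21L, 1e-3, 0.1)
  expect_error(cddpm:::check_schedule_match(ck$schedule_fingerprint, s2),
               "different noise schedule")
  unlink(f)
})
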
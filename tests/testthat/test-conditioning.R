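test_that("patient-wise normalization maps to [-1,1] and round-trips", {
  g <- list(matrix(c(0, 50, 100, 150), 2, 2), matrix(c(25, 75, 125, 200), 2, 2))
  nn <- normalize_patientwise(g)
  expect_equal(nn[[1]][2, 2] , 0.5)           # 150 of [0, 200]
  expect_equal(nn[[1]][1, 1], -1)
  expect_equal(nn[[2]][2, 2], 1)
  expect_equal(nn[[1]][1, 2], 0)              # 100 is the midpoint of [0, 200]
  back <- denormalize_patientwise(nn)
  for (i in 1:2) expect_equal(back[[i]], g[[i]], tolerance = 1e-6)
  # constant group maps to zeros without division by zero
  cc <- normalize_patientwise(list(matrix(7, 3, 3)))
  expect_equal(cc[[1]], matrix(0, 3, 3))
  expect_error(normalize_patientwise(list()), "empty")
})

test_that("SR condition: factor-1 identity and constants preserved", {
  x0 <- tiny_phantoms(1, size = 16)[[1]]$image
  p1 <- make_sr_condition(x0, 1)
  expect_equal(p1$y, x0, tolerance = 1e-6)
  cst <- matrix(0.4, 16, 16)
  for (f in c(2, 2 * sqrt(2), 4)) {
    pc <- make_sr_condition(cst, f)
    expect_equal(pc$y, cst, tolerance = 1e-9)
  }
  expect_error(make_sr_condition(x0, 0.5), "factor")
})

test_that("SR factor-4 intermediate equals the block-mean oracle", {
  set.seed(13)
  x0 <- matrix(runif(128 * 128, -1, 1), 128, 128)
  h <- 32L
  inter <- cddpm:::resize_area(x0, h, h)
  # direct 4x4 block means
  oracle <- matrix(0, h, h)
  for (i in seq_len(h)) for (j in seq_len(h))
    oracle[i, j] <- mean(x0[(4 * i - 3):(4 * i), (4 * j - 3):(4 * j)])
  expect_equal(inter, oracle, tolerance = 1e-12)
  pr <- make_sr_condition(x0, 4)
  expect_identical(pr$meta$low_res, c(32L, 32L))
  expect_s3_class(pr, "condition_pair")
})

test_that("noise condition: no-op, Gaussian moments and binomial salt-and-pepper count", {
  x0 <- tiny_phantoms(1, size = 16)[[1]]$image
  p0 <- make_noise_condition(x0, 0, 0)
  expect_identical(p0$y, x0)
  # Gaussian-only moments on an interior-valued image (no clipping)
  flat <- matrix(0, 320, 320)   # 102400 pixels
  pg <- make_noise_condition(flat, gauss_sigma = 0.1, sp_amount = 0, seed = 5L)
  d <- pg$y - flat
  n <- length(d)
  expect_lt(abs(mean(d)), 3 * 0.1 / sqrt(n))
  expect_lt(abs(sd(d) - 0.1), 3 * 0.1 / sqrt(2 * n))
  # salt-and-pepper replacement count ~ Binomial(16384, 0.05)
  big <- matrix(0, 128, 128)
  ps <- make_noise_condition(big, gauss_sigma = 0, sp_amount = 0.05, seed = 6L)
  n_rep <- sum(ps$y != 0)
  expect_lt(abs(n_rep - 819.2), 4 * sqrt(16384 * 0.05 * 0.95))
  expect_identical(ps$meta$n_sp, n_rep)
  expect_true(all(ps$y[ps$y != 0] %in% c(-1, 1)))
  expect_error(make_noise_condition(x0, -1, 0), "gauss_sigma")
  expect_error(make_noise_condition(x0, 0, 1), "sp_amount")
})

test_that("inpainting: determinism in test mode, geometry, and invariants", {
  x0 <- tiny_phantoms(1, size = 16)[[1]]$image
  # fixed-size single rectangle: exactly 1/16 of pixels masked
  sp <- mask_spec("rectangles", count = c(1L, 1L), size = c(0.25, 0.25),
                  seed = 3L)
  pr <- make_inpaint_condition(x0, sp, mode = "test")
  expect_equal(mean(pr$mask), 0.0625)
  expect_true(all(pr$y[pr$mask] == 0))
  expect_identical(pr$y[!pr$mask], x0[!pr$mask])
  # test mode: identical masks across calls; train mode: fresh masks
  pr2 <- make_inpaint_condition(x0, sp, mode = "test")
  expect_identical(pr$mask, pr2$mask)
  set.seed(1)
  a <- make_inpaint_condition(x0, mask_spec(seed = 1L), mode = "train")
  b <- make_inpaint_condition(x0, mask_spec(seed = 1L), mode = "train")
  expect_false(identical(a$mask, b$mask))
  # ellipse masks are supported and non-empty
  pe <- make_inpaint_condition(x0, mask_spec("ellipses", seed = 2L),
                               mode = "test")
  expect_gt(mean(pe$mask), 0)
  expect_lte(mean(pe$mask), 0.5)
})

test_that("condition_pair constructor enforces its invariants", {
  x0 <- matrix(0.5, 4, 4)
  expect_error(condition_pair(x0, matrix(2, 4, 4), "SR"), "\\[-1, 1\\]")
  expect_error(condition_pair(x0, matrix(0.5, 3, 3), "SR"), "shape")
  bad_y <- x0
  bad_y[1, 1] <- 0.1
  m <- matrix(FALSE, 4, 4)
  m[2, 2] <- TRUE
  expect_error(condition_pair(x0, bad_y, "INPAINT", mask = m), "outside the mask")
  y <- x0
  y[2, 2] <- 0
  p <- condition_pair(x0, y, "INPAINT", mask = m)
  expect_identical(sum(p$y != p$x0), 1L)
})
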
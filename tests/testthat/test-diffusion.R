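test_that("q_sample trivial cases and determinism", {
  s <- linear_beta_schedule(50L, 1e-3, 0.05)
  x0 <- tiny_phantoms(1)[[1]]$image
  z <- x0 * 0
  expect_equal(q_sample(x0, 7L, z, s), sqrt(s$alpha_bar[7]) * x0)
  eps <- matrix(rnorm(length(x0)), nrow(x0))
  expect_equal(q_sample(z, 7L, eps, s), sqrt(1 - s$alpha_bar[7]) * eps)
  expect_identical(q_sample(x0, 7L, eps, s), q_sample(x0, 7L, eps, s))
  expect_error(q_sample(x0, 7L, eps[1:4, 1:4], s), "shape mismatch")
  expect_error(q_sample(x0, 0L, eps, s), "t must be in")
})

test_that("closed-form marginal matches the stepwise chain by Monte Carlo", {
  # scalar pixels, 1e5 draws, 3-SE agreement of mean and variance
  s <- linear_beta_schedule(10L, 0.05, 0.2)
  x0 <- matrix(0.6, 1, 1)
  n <- 1e5
  t <- 5L
  set.seed(101)
  stepwise <- vapply(seq_len(n), function(i)
    q_sample_stepwise(x0, t, s)[1, 1], numeric(1))
  ab <- s$alpha_bar[t]
  m_th <- sqrt(ab) * 0.6
  v_th <- 1 - ab
  se_mean <- sqrt(v_th / n)
  se_var <- v_th * sqrt(2 / (n - 1))
  expect_lt(abs(mean(stepwise) - m_th), 3 * se_mean)
  expect_lt(abs(var(stepwise) - v_th), 3 * se_var)
  # zero-signal marginal is N(0, 1 - alpha_bar_t)
  set.seed(102)
  z <- vapply(seq_len(n), function(i)
    q_sample_stepwise(matrix(0, 1, 1), t, s)[1, 1], numeric(1))
  expect_lt(abs(mean(z)), 3 * se_mean)
  expect_lt(abs(var(z) - v_th), 3 * se_var)
})

test_that("q_sample_stepwise is reproducible from its seed and leaves the RNG alone", {
  s <- linear_beta_schedule(10L, 0.05, 0.2)
  x0 <- matrix(0.3, 4, 4)
  set.seed(1)
  before <- rnorm(1)
  set.seed(1)
  a <- q_sample_stepwise(x0, 5L, s, rng_seed = 42L)
  b <- q_sample_stepwise(x0, 5L, s, rng_seed = 42L)
  after <- rnorm(1)
  expect_identical(a, b)
  expect_identical(before, after)
})

test_that("q_posterior agrees with a grid-based Bayes oracle on scalars", {
  s <- linear_beta_schedule(10L, 0.1, 0.2)
  set.seed(5)
  for (t in c(1L, 4L, 8L)) {
    x0v <- runif(1, -0.8, 0.8)
    xt1v <- q_sample(matrix(x0v, 1, 1), t + 1L,
                     matrix(rnorm(1), 1, 1), s)[1, 1]
    got <- q_posterior(matrix(x0v, 1, 1), matrix(xt1v, 1, 1), t, s)
    orc <- oracle_posterior_grid(x0v, xt1v, t, s)
    expect_equal(got$mean[1, 1], orc$mean, tolerance = 1e-6)
    expect_equal(got$var, orc$var, tolerance = 1e-6)
  }
})

test_that("q_posterior linearity and variance single-sourcing", {
  s <- linear_beta_schedule(10L, 0.1, 0.2)
  cimg <- matrix(0.4, 3, 3)
  for (t in c(0L, 3L)) {
    co <- posterior_coefficients(s, t)
    got <- q_posterior(cimg, cimg, t, s)
    expect_equal(got$mean, cimg * (co$coef_x0 + co$coef_xt1))
    expect_identical(got$var, co$var)
  }
})

test_that("mu_theta_from_eps identities", {
  s <- linear_beta_schedule(20L, 0.01, 0.1)
  set.seed(9)
  x0 <- tiny_phantoms(1, size = 8)[[1]]$image
  eps <- matrix(rnorm(64), 8, 8)
  for (t in c(2L, 10L, 20L)) {
    xt <- q_sample(x0, t, eps, s)
    # with the true noise, the reverse mean equals the forward posterior mean
    mu <- mu_theta_from_eps(xt, eps, t, s)
    qp <- q_posterior(x0, xt, t - 1L, s)
    expect_equal(mu, qp$mean, tolerance = 1e-6)
    # inversion recovers x0 exactly
    expect_equal(predicted_x0_from_eps(xt, eps, t, s), x0, tolerance = 1e-9)
  }
  xt <- q_sample(x0, 5L, eps, s)
  expect_equal(mu_theta_from_eps(xt, xt * 0, 5L, s), xt / sqrt(s$alpha[5]))
})

test_that("p_sample_step noise conventions and determinism", {
  s0 <- linear_beta_schedule(10L, 0.1, 0.2, sigma_mode = "zero")
  s <- linear_beta_schedule(10L, 0.1, 0.2)
  set.seed(3)
  xt <- matrix(rnorm(64), 8, 8)
  y <- matrix(0, 8, 8)
  eps <- matrix(rnorm(64), 8, 8)
  mod <- oracle_predictor(eps)
  # sigma-mode zero: sample == mean
  st <- p_sample_step(xt, y, 5L, mod, s0, rng_seed = 1L)
  expect_identical(st$sample, st$mean)
  # t=1: no noise added even with sigma > 0
  st1 <- p_sample_step(xt, y, 1L, mod, s, rng_seed = 1L)
  expect_identical(st1$sample, st1$mean)
  # fixed seed -> bit-identical repeat
  a <- p_sample_step(xt, y, 5L, mod, s, rng_seed = 11L)
  b <- p_sample_step(xt, y, 5L, mod, s, rng_seed = 11L)
  expect_identical(a$sample, b$sample)
  expect_false(identical(a$sample, a$mean))
  # malformed model output is reported against the model
  bad <- as_noise_predictor(function(xt, y, t) xt[1:2, 1:2], name = "bad")
  expect_error(p_sample_step(xt, y, 5L, bad, s), "bad")
})

test_that("oracle noise predictor round-trip recovers x0 on the sigma=0 path", {
  # the cheating predictor returns the noise consistent with the current
  # state; each reverse mean then equals the forward-posterior mean, and the
  # t=1 posterior collapses onto x0 exactly
  s <- linear_beta_schedule(200L, 1e-4, 0.02, sigma_mode = "zero")
  x0 <- tiny_phantoms(1, size = 16)[[1]]$image
  set.seed(21)
  eps <- matrix(rnorm(length(x0)), nrow(x0))
  x <- q_sample(x0, s$T, eps, s)
  mod <- consistent_oracle(x0, s)
  for (t in seq(s$T, 1L)) {
    x <- p_sample_step(x, x0 * 0, t, mod, s)$sample
  }
  expect_lt(max(abs(x - x0)), 1e-3)
})

test_that("p_sample_loop determinism and trajectory contract", {
  s <- linear_beta_schedule(10L, 0.05, 0.2)
  y <- matrix(0, 8, 8)
  mod <- zero_predictor()
  a <- p_sample_loop(y, mod, s, rng_seed = 5L)
  b <- p_sample_loop(y, mod, s, rng_seed = 5L)
  expect_identical(a, b)
  expect_true(all(a >= -1 & a <= 1))
  tr <- p_sample_loop(y, mod, s, rng_seed = 5L, keep_trajectory = TRUE)
  expect_length(tr$trajectory, s$T + 1L)
  expect_identical(tr$x0, a)
  # a NaN-producing model aborts with the offending timestep
  nanmod <- as_noise_predictor(function(xt, y, t) xt * NaN, name = "nan")
  expect_error(p_sample_loop(y, nanmod, s, rng_seed = 1L), "t=10")
})

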
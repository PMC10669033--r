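test_that("clamp reproduces the three saturating branches exactly", {
  expect_identical(clamp_unit(1.5), 1)
  expect_identical(clamp_unit(-3), -1)
  expect_identical(clamp_unit(0.2), 0.2)
  expect_identical(clamp_unit(c(-2, -1, 0, 1, 2)), c(-1, -1, 0, 1, 1))
})

test_that("simple_loss of oracle and zero predictors", {
  s <- linear_beta_schedule(50L, 1e-3, 0.05)
  x0 <- tiny_phantoms(1, size = 8)[[1]]$image
  y <- x0
  set.seed(2)
  eps <- matrix(rnorm(64), 8, 8)
  expect_equal(simple_loss(oracle_predictor(eps), x0, y, 10L, eps, s), 0)
  expect_equal(simple_loss(zero_predictor(), x0, y, 10L, eps, s), mean(eps^2))
  # expectation over many draws is ~1 for the zero predictor
  set.seed(3)
  ls <- replicate(200, {
    e <- matrix(rnorm(64), 8, 8)
    simple_loss(zero_predictor(), x0, y, 10L, e, s)
  })
  expect_lt(abs(mean(ls) - 1), 4 * sd(ls) / sqrt(length(ls)))
  expect_error(simple_loss(zero_predictor(), x0, y, 51L, eps, s), "t must be")
})

test_that("gaussian_kl closed form matches quadrature and basic values", {
  expect_equal(gaussian_kl(matrix(0.3, 2, 2), 0.5, matrix(0.3, 2, 2), 0.5), 0)
  expect_equal(gaussian_kl(0, 1, 1, 1), 0.5)
  set.seed(4)
  for (i in 1:5) {
    m1 <- runif(1, -2, 2); m2 <- runif(1, -2, 2)
    v1 <- runif(1, 0.2, 3); v2 <- runif(1, 0.2, 3)
    expect_equal(gaussian_kl(m1, v1, m2, v2),
                 oracle_kl_quadrature(m1, v1, m2, v2), tolerance = 1e-6)
  }
  expect_error(gaussian_kl(0, -1, 0, 1), "positive")
  expect_gte(gaussian_kl(0.2, 0.7, -0.4, 1.3), 0)
})

test_that("vlb_term: mean-space and noise-space forms agree up to a model-independent constant", {
  s <- linear_beta_schedule(30L, 0.01, 0.1)
  x0 <- tiny_phantoms(1, size = 8)[[1]]$image
  y <- x0
  set.seed(6)
  for (t in c(1L, 10L, 25L)) {
    eps <- matrix(rnorm(64), 8, 8)
    xt1 <- q_sample(x0, t + 1L, eps, s)
    modA <- as_noise_predictor(function(xt, y, t) 0.3 * xt, "A")
    modB <- as_noise_predictor(function(xt, y, t) -0.2 * y + 0.1, "B")
    ra <- vlb_term(modA, x0, y, t, xt1, s)
    rb <- vlb_term(modB, x0, y, t, xt1, s)
    # difference between the two quadratic forms is invariant to the model
    expect_equal(ra$mean_quad - ra$eps_quad, rb$mean_quad - rb$eps_quad,
                 tolerance = 1e-8)
    expect_gte(ra$value, 0)
    expect_gte(rb$value, 0)
    # oracle predictor with matched variances: KL reduces to the pure
    # variance-mismatch constant, zero when sigma^2 = beta_tilde
    st <- linear_beta_schedule(30L, 0.01, 0.1, sigma_mode = "beta_tilde")
    ro <- vlb_term(oracle_predictor(eps), x0, y, t, xt1, st)
    expect_equal(ro$value, 0, tolerance = 1e-7)
  }
  expect_error(vlb_term(zero_predictor(), x0, y, 0L, x0, s), "l0_term")
  expect_error(vlb_term(zero_predictor(), x0, y, 30L, x0, s), "l0_term")
})

test_that("lT_term closed form, bound and monotonicity", {
  s <- linear_beta_schedule(2000L, 1e-4, 0.02)
  z <- matrix(0, 4, 4)
  abT <- s$alpha_bar[s$T]
  v <- 1 - abT
  expect_equal(lT_term(z, s), 16 * 0.5 * (v - 1 - log(v)))
  # tiny for any x0 in [-1,1] under the long default schedule
  ones <- matrix(1, 4, 4)
  expect_lt(lT_term(ones, s) / 16, 1e-3)
  # monotone in |x0|
  expect_gt(lT_term(ones, s), lT_term(0.5 * ones, s))
})

test_that("discretized decoder: bin masses sum to one in open mode", {
  centers <- seq(-1, 1, length.out = 256)
  for (cfg in list(c(0.0, 0.5), c(0.3, 0.05), c(-0.97, 1e-3), c(2.0, 0.2))) {
    mu <- matrix(cfg[1], 1, 1)
    sg <- cfg[2]
    masses <- vapply(centers, function(cv)
      exp(-l0_term(mu, sg, matrix(cv, 1, 1), edges = "open")), numeric(1))
    expect_equal(sum(masses), 1, tolerance = 1e-9)
  }
})

test_that("discretized decoder: literal clamping loses tail mass, open mode keeps it", {
  mu <- matrix(0.9, 1, 1)
  top <- matrix(1, 1, 1)
  nll_open <- l0_term(mu, 0.5, top, edges = "open")
  nll_lit <- l0_term(mu, 0.5, top, edges = "literal")
  expect_lt(nll_open, nll_lit)   # open bin holds the whole upper tail
  expect_error(l0_term(mu, 0.5, top, delta = 0), "delta")
  expect_error(l0_term(mu, -1, top), "sigma")
})

test_that("decoder NLL is minimized at mu = x0 for interior pixels", {
  x0 <- matrix(0.2, 1, 1)
  nll <- vapply(seq(-0.5, 0.9, by = 0.05), function(m)
    l0_term(matrix(m, 1, 1), 0.1, x0), numeric(1))
  expect_equal(which.min(nll), which.min(abs(seq(-0.5, 0.9, by = 0.05) - 0.2)))
})

test_that("decoder NLL stays finite at very small sigma (log-space path)", {
  x0 <- matrix(c(-1, -0.5, 0.5, 1), 2, 2)
  v <- l0_term(matrix(0.1, 2, 2), 1e-4, x0)
  expect_true(is.finite(v))
  v2 <- l0_term(x0, 1e-4, x0)
  expect_true(is.finite(v2))
})
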
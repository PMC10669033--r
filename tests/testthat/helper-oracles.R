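# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths for the quantities they check.

# cumulative signal product via Kahan-compensated summation of log1p terms
oracle_alpha_bar <- function(T_steps, beta_start, beta_end) {
  beta <- if (T_steps == 1L) beta_start else
    seq(beta_start, beta_end, length.out = T_steps)
  s <- 0
  comp <- 0
  out <- numeric(T_steps)
  for (t in seq_len(T_steps)) {
    term <- log1p(-beta[t]) - comp
    tot <- s + term
    comp <- (tot - s) - term
    s <- tot
    out[t] <- exp(s)
  }
  out
}

# brute-force Bayes rule on a 1-D grid: posterior of x_t given x_{t+1}, x_0
# for scalar "pixels", from the one-step likelihood and the closed marginal
oracle_posterior_grid <- function(x0, xt1, t, s, n_grid = 20001L, span = 8) {
  ab_t <- if (t == 0L) 1 else s$alpha_bar[t]
  prior_mu <- sqrt(ab_t) * x0
  prior_sd <- sqrt(max(1 - ab_t, 1e-300))
  g <- seq(prior_mu - span * max(prior_sd, 1), prior_mu + span * max(prior_sd, 1),
           length.out = n_grid)
  lik <- stats::dnorm(xt1, mean = sqrt(s$alpha[t + 1L]) * g,
                      sd = sqrt(s$beta[t + 1L]))
  pri <- if (t == 0L) as.numeric(g == g[which.min(abs(g - x0))]) else
    stats::dnorm(g, mean = prior_mu, sd = prior_sd)
  w <- lik * pri
  w <- w / sum(w)
  mu <- sum(w * g)
  list(mean = mu, var = sum(w * (g - mu)^2))
}

# KL of two scalar Gaussians by quadrature on a +-12 sigma grid
oracle_kl_quadrature <- function(m1, v1, m2, v2, n_grid = 200001L) {
  sd1 <- sqrt(v1)
  g <- seq(m1 - 12 * sd1, m1 + 12 * sd1, length.out = n_grid)
  dx <- g[2] - g[1]
  p <- stats::dnorm(g, m1, sd1)
  lq <- stats::dnorm(g, m2, sqrt(v2), log = TRUE)
  lp <- stats::dnorm(g, m1, sd1, log = TRUE)
  sum(p * (lp - lq)) * dx
}

oracle_predictor <- function(eps) {
  as_noise_predictor(function(xt, y, t) eps, name = "oracle_eps")
}

# cheating predictor for reverse-pass round trips: returns the noise
# consistent with the *current* state, (x_t - sqrt(ab_t) x0) / sqrt(1 - ab_t)
consistent_oracle <- function(x0, s) {
  as_noise_predictor(function(xt, y, t) {
    ab <- s$alpha_bar[t]
    (xt - sqrt(ab) * x0) / sqrt(1 - ab)
  }, name = "oracle_consistent")
}

zero_predictor <- function() {
  as_noise_predictor(function(xt, y, t) xt * 0, name = "zero")
}

# small deterministic phantom batch for metric/round-trip tests
tiny_phantoms <- function(n = 4L, size = 16L, seed = 7L,
                          texture_strength = 0.05) {
  generate_phantoms(phantom_spec(image_size = size, n_images = n, seed = seed,
                                 texture_strength = texture_strength))
}
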
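# Training objectives and variational-bound diagnostics.
# Training uses only the simplified epsilon-prediction loss; the per-term
# variational bound (KL terms and the discretized decoder) is diagnostic.

#' Clamp to the unit interval \[-1, 1\]
#'
#' The decoder's integration-limit function: identity inside (-1, 1),
#' saturating at the boundaries.
#' @param x Numeric vector/matrix.
#' @export
clamp_unit <- function(x) pmin(pmax(x, -1), 1)

#' Simplified diffusion training loss
#'
#' The epsilon-prediction objective
#' \eqn{\lVert \epsilon - \epsilon_\theta(\sqrt{\bar\alpha_t} x_0 +
#' \sqrt{1-\bar\alpha_t}\,\epsilon,\, y,\, t) \rVert^2}, reduced as the
#' per-pixel mean so its magnitude is resolution independent (a pure
#' rescaling of the gradient relative to the unreduced squared norm).
#'
#' @param model A noise predictor.
#' @param x0 Clean image.
#' @param y Condition image.
#' @param t Timestep in `1..T` (the caller draws it uniformly in training).
#' @param eps Noise draw, same shape as `x0`.
#' @param s A `noise_schedule`.
#' @return Scalar loss value.
#' @export
simple_loss <- function(model, x0, y, t, eps, s) {
  xt <- q_sample(x0, t, eps, s)
  eps_hat <- predict_noise(model, xt, y, t)
  mean((eps - eps_hat)^2)
}

#' KL divergence between diagonal Gaussians
#'
#' Closed form, summed over pixels, in nats:
#' \eqn{\sum_i \frac12\left(\log\frac{v_2}{v_1} + \frac{v_1 + (m_{1i}-m_{2i})^2}{v_2} - 1\right)}.
#'
#' @param mean1,mean2 Mean images (same shape) or scalars.
#' @param var1,var2 Positive scalar variances (isotropic).
#' @export
gaussian_kl <- function(mean1, var1, mean2, var2) {
  if (!(is.numeric(var1) && is.numeric(var2) && var1 > 0 && var2 > 0))
    stop("variances must be positive")
  check_same_shape(mean1, mean2, "mean1", "mean2")
  n <- length(mean1)
  0.5 * (n * (log(var2 / var1) + var1 / var2 - 1) +
           sum((mean1 - mean2)^2) / var2)
}

#' Variational-bound term L_t for 0 < t < T
#'
#' KL divergence between the forward posterior `q(x_t | x_{t+1}, x_0)` and
#' the model's reverse Gaussian `p(x_t | x_{t+1}, y)` with variance
#' \eqn{\sigma^2_{t+1}}. The report also carries the two equivalent
#' quadratic forms of the bound: `mean_quad`
#' (\eqn{\lVert\tilde\mu - \mu_\theta\rVert^2 / 2\sigma^2_{t+1}}) and
#' `eps_quad` (the same quantity rewritten in noise space with coefficient
#' \eqn{\beta_{t+1}^2 / (2\sigma^2_{t+1}\alpha_{t+1}(1-\bar\alpha_{t+1}))});
#' both omit the same model-independent additive constant.
#'
#' @param model A noise predictor.
#' @param x0 Clean image.
#' @param y Condition image.
#' @param t Term index with `0 < t < T`.
#' @param xt1 A sample of the forward process at step `t + 1`.
#' @param s A `noise_schedule`.
#' @return A `vlb_term_report`: list with `t`, `term_kind`, `value` (exact
#'   KL, nats), `mean_quad`, `eps_quad`.
#' @export
vlb_term <- function(model, x0, y, t, xt1, s) {
  if (t <= 0L || t >= s$T)
    stop("vlb_term requires 0 < t < T; use l0_term / lT_term at the ends")
  q <- q_posterior(x0, xt1, t, s)
  eps_hat <- predict_noise(model, xt1, y, t + 1L)
  mu_theta <- mu_theta_from_eps(xt1, eps_hat, t + 1L, s)
  sig2 <- s$sigma2[t + 1L]
  if (sig2 <= 0) stop("vlb_term needs a positive sampling variance")
  value <- gaussian_kl(q$mean, q$var, mu_theta, sig2)
  ab1 <- s$alpha_bar[t + 1L]
  eps_true <- (xt1 - sqrt(ab1) * x0) / sqrt(1 - ab1)
  coef <- s$beta[t + 1L]^2 / (2 * sig2 * s$alpha[t + 1L] * (1 - ab1))
  structure(list(
    t = as.integer(t), term_kind = "Lt", value = value,
    mean_quad = sum((q$mean - mu_theta)^2) / (2 * sig2),
    eps_quad = coef * sum((eps_true - eps_hat)^2)
  ), class = "vlb_term_report")
}

#' Prior-matching term L_T (diagnostic)
#'
#' KL between the forward marginal at the last step,
#' `q(x_T | x_0) = N(sqrt(alpha_bar_T) x_0, (1 - alpha_bar_T) I)`, and the
#' standard normal prior. A constant with no learnable parameters; near zero
#' for long schedules where \eqn{\bar\alpha_T \approx 0}.
#'
#' @param x0 Clean image.
#' @param s A `noise_schedule`.
#' @return KL in nats (summed over pixels).
#' @export
lT_term <- function(x0, s) {
  check_image(x0)
  abT <- s$alpha_bar[s$T]
  v <- 1 - abT
  0.5 * (abT * sum(x0^2) + length(x0) * (v - 1 - log(v)))
}

# log(Phi(zb) - Phi(za)) computed stably for za < zb, supporting +-Inf bounds
log_gauss_cdf_diff <- function(za, zb) {
  out <- numeric(length(za))
  lo_inf <- is.infinite(za) & za < 0
  hi_inf <- is.infinite(zb) & zb > 0
  both_neg <- !lo_inf & zb <= 0
  both_pos <- !hi_inf & za >= 0
  mid <- !(lo_inf | hi_inf | both_neg | both_pos)
  if (any(lo_inf & hi_inf)) out[lo_inf & hi_inf] <- 0
  i <- lo_inf & !hi_inf
  if (any(i)) out[i] <- stats::pnorm(zb[i], log.p = TRUE)
  i <- hi_inf & !lo_inf
  if (any(i)) out[i] <- stats::pnorm(za[i], lower.tail = FALSE, log.p = TRUE)
  if (any(both_neg)) {
    la <- stats::pnorm(za[both_neg], log.p = TRUE)
    lb <- stats::pnorm(zb[both_neg], log.p = TRUE)
    out[both_neg] <- lb + log1p(-exp(la - lb))
  }
  if (any(both_pos)) {
    la <- stats::pnorm(za[both_pos], lower.tail = FALSE, log.p = TRUE)
    lb <- stats::pnorm(zb[both_pos], lower.tail = FALSE, log.p = TRUE)
    out[both_pos] <- la + log1p(-exp(lb - la))
  }
  if (any(mid))
    out[mid] <- log(stats::pnorm(zb[mid]) - stats::pnorm(za[mid]))
  out
}

#' Discretized Gaussian decoder negative log-likelihood L_0
#'
#' Likelihood of 8-bit pixel data under the reverse process's final Gaussian:
#' each pixel contributes the Gaussian mass of its quantization bin,
#' \eqn{\int_{x-\delta}^{x+\delta} N(u; \mu, \sigma^2)\,du}, with bin
#' half-width `delta` on the \[-1, 1\] scale. Two edge-bin conventions are
#' supported: `"open"` (default) extends the outermost bins to infinity so
#' the 256 bin masses sum to one; `"literal"` clamps the integration limits
#' to \[-1, 1\] exactly (the saturating limit function), losing the tail
#' mass. CDF differences are evaluated in log space, stable down to very
#' small `sigma`.
#'
#' @param mu Decoder mean image.
#' @param sigma Positive scalar standard deviation.
#' @param x0 Observed image on the 8-bit lattice mapped into \[-1, 1\].
#' @param delta Half bin width; default `1/255` (8-bit quantization).
#' @param edges Edge-bin convention, `"open"` or `"literal"`.
#' @return Negative log-likelihood in nats (summed over pixels).
#' @export
l0_term <- function(mu, sigma, x0, delta = 1 / 255,
                    edges = c("open", "literal")) {
  edges <- match.arg(edges)
  if (!(is.numeric(delta) && length(delta) == 1L && delta > 0))
    stop("`delta` must be a positive scalar")
  if (!(is.numeric(sigma) && length(sigma) == 1L && sigma > 0))
    stop("`sigma` must be a positive scalar")
  check_same_shape(mu, x0, "mu", "x0")
  lower <- x0 - delta
  upper <- x0 + delta
  if (edges == "literal") {
    lower <- clamp_unit(lower)
    upper <- clamp_unit(upper)
  } else {
    lower[lower <= -1] <- -Inf
    upper[upper >= 1] <- Inf
  }
  lp <- log_gauss_cdf_diff((lower - mu) / sigma, (upper - mu) / sigma)
  -sum(lp)
}
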
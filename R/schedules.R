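#' Linear variance schedule for the diffusion forward process
#'
#' Constructs every per-timestep constant of a Gaussian diffusion chain with
#' variances \eqn{\beta_t} linearly interpolated between `beta_start` and
#' `beta_end` over `T_steps` steps. All derived sequences are computed once
#' here and reused by every other function in the package:
#' \eqn{\alpha_t = 1 - \beta_t}, the cumulative signal level
#' \eqn{\bar\alpha_t = \prod_{i \le t} \alpha_i}, the forward-posterior
#' variance \eqn{\tilde\beta_t = \beta_t (1-\bar\alpha_{t-1})/(1-\bar\alpha_t)},
#' and the sampling variance \eqn{\sigma_t^2}.
#'
#' Timesteps are 1-based throughout the public API (`t = 1..T`). The empty
#' product convention \eqn{\bar\alpha_0 = 1} is used wherever a `t = 0`
#' quantity is needed. Values are stored in double precision;
#' \eqn{\bar\alpha_T} underflows single precision for long schedules.
#'
#' @param T_steps Number of diffusion steps (positive integer). Default 2000.
#' @param beta_start Variance at `t = 1`. Default `1e-4`.
#' @param beta_end Variance at `t = T`. Default `0.02`.
#' @param sigma_mode Sampling variance convention: `"beta"` sets
#'   \eqn{\sigma_t^2 = \beta_t} (the default), `"beta_tilde"` uses the
#'   forward-posterior variance, `"zero"` gives a deterministic mean path
#'   (useful in tests only).
#' @return An object of class `noise_schedule`: a list with elements `T`,
#'   `beta`, `alpha`, `alpha_bar`, `posterior_variance`, `sigma2`,
#'   `sigma_mode`, `beta_start`, `beta_end`.
#' @examples
#' s <- linear_beta_schedule(2000)
#' s$beta[1]; s$beta[2000]
#' @export
linear_beta_schedule <- function(T_steps = 2000L, beta_start = 1e-4,
                                 beta_end = 0.02,
                                 sigma_mode = c("beta", "beta_tilde", "zero")) {
  sigma_mode <- match.arg(sigma_mode)
  if (length(T_steps) != 1L || is.na(T_steps) || T_steps < 1 ||
      T_steps != as.integer(T_steps)) {
    stop("`T_steps` must be a positive integer")
  }
  T_steps <- as.integer(T_steps)
  if (!(beta_start > 0 && beta_start <= beta_end && beta_end < 1)) {
    stop("need 0 < beta_start <= beta_end < 1")
  }
  beta <- if (T_steps == 1L) beta_start else
    seq(beta_start, beta_end, length.out = T_steps)
  alpha <- 1 - beta
  # log-domain cumulative product: robust for long schedules
  alpha_bar <- exp(cumsum(log(alpha)))
  alpha_bar_prev <- c(1, alpha_bar[-T_steps])   # alpha_bar[0] := 1
  posterior_variance <- beta * (1 - alpha_bar_prev) / (1 - alpha_bar)
  sigma2 <- switch(sigma_mode,
    beta = beta,
    beta_tilde = posterior_variance,
    zero = rep(0, T_steps))
  structure(list(
    T = T_steps, beta = beta, alpha = alpha, alpha_bar = alpha_bar,
    posterior_variance = posterior_variance, sigma2 = sigma2,
    sigma_mode = sigma_mode, beta_start = beta_start, beta_end = beta_end
  ), class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf(
    "<noise_schedule> T=%d, beta in [%.3g, %.3g], sigma_mode=%s, alpha_bar[T]=%.4g\n",
    x$T, x$beta_start, x$beta_end, x$sigma_mode, x$alpha_bar[x$T]))
  invisible(x)
}

# alpha_bar with the empty-product convention alpha_bar[0] = 1
alpha_bar_at <- function(s, t) {
  if (t == 0L) 1 else s$alpha_bar[t]
}

#' Coefficients of the forward posterior q(x_t | x_{t+1}, x_0)
#'
#' The forward posterior is Gaussian with mean
#' `coef_x0 * x0 + coef_xt1 * x_{t+1}` and variance `var`:
#' \deqn{\tilde\mu_{t+1} = \frac{\sqrt{\bar\alpha_t}\,\beta_{t+1}}{1-\bar\alpha_{t+1}} x_0
#'   + \frac{\sqrt{\alpha_{t+1}}\,(1-\bar\alpha_t)}{1-\bar\alpha_{t+1}} x_{t+1}}
#' with \eqn{\tilde\beta_{t+1} = \beta_{t+1}(1-\bar\alpha_t)/(1-\bar\alpha_{t+1})}.
#' `t = 0` is valid via the convention \eqn{\bar\alpha_0 = 1}.
#'
#' @param s A `noise_schedule`.
#' @param t Target timestep, `0 <= t <= T-1`; the posterior conditions on the
#'   sample at step `t + 1`.
#' @return List with numeric scalars `coef_x0`, `coef_xt1`, `var`.
#' @export
posterior_coefficients <- function(s, t) {
  stopifnot(inherits(s, "noise_schedule"))
  if (length(t) != 1L || t < 0L || t + 1L > s$T) {
    stop(sprintf("t must satisfy 0 <= t <= T-1 = %d", s$T - 1L))
  }
  t <- as.integer(t)
  ab_t <- alpha_bar_at(s, t)
  ab_t1 <- s$alpha_bar[t + 1L]
  list(
    coef_x0 = sqrt(ab_t) * s$beta[t + 1L] / (1 - ab_t1),
    coef_xt1 = sqrt(s$alpha[t + 1L]) * (1 - ab_t) / (1 - ab_t1),
    var = s$posterior_variance[t + 1L]
  )
}
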
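# Forward noising, forward posterior, reverse step and ancestral sampling.
# Images are H x W numeric matrices, or H x W x N arrays for batches.

check_image <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || !(is.matrix(x) || (is.array(x) && length(dim(x)) == 3L)))
    stop(sprintf("`%s` must be a numeric matrix or H x W x N array", name))
  if (!all(is.finite(x)))
    stop(sprintf("`%s` contains non-finite values", name))
  invisible(x)
}

check_same_shape <- function(a, b, na = "a", nb = "b") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("shape mismatch: `%s` is %s but `%s` is %s", na,
                 paste(dim(a), collapse = "x"), nb, paste(dim(b), collapse = "x")))
  invisible(NULL)
}

check_t <- function(t, s) {
  if (length(t) != 1L || is.na(t) || t < 1L || t > s$T)
    stop(sprintf("t must be in 1..T = %d, got %s", s$T, format(t)))
  as.integer(t)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards. NULL seed = use current RNG.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Small deterministic seed derivation, kept below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483587)
}

#' Sample the forward process at an arbitrary timestep (closed form)
#'
#' The Gaussian noising chain admits the closed-form marginal
#' \eqn{x_t = \sqrt{\bar\alpha_t}\, x_0 + \sqrt{1-\bar\alpha_t}\, \epsilon}
#' with \eqn{\epsilon \sim N(0, I)}. Deterministic given `eps`.
#'
#' @param x0 Clean image (matrix or H x W x N array), values nominally in
#'   \[-1, 1\].
#' @param t Timestep in `1..T`.
#' @param eps Noise draw, same shape as `x0`.
#' @param s A [linear_beta_schedule()] object.
#' @return The noised image, same shape as `x0`.
#' @export
q_sample <- function(x0, t, eps, s) {
  check_image(x0); check_image(eps); check_same_shape(x0, eps, "x0", "eps")
  t <- check_t(t, s)
  ab <- s$alpha_bar[t]
  sqrt(ab) * x0 + sqrt(1 - ab) * eps
}

#' Sample the forward process step by step (test oracle)
#'
#' Applies the one-step transition
#' \eqn{x_i = \sqrt{1-\beta_i}\, x_{i-1} + \sqrt{\beta_i}\, \epsilon_i}
#' iteratively `t` times. Distributionally equivalent to [q_sample()]; kept
#' as an independent oracle for testing the closed-form marginal.
#'
#' @inheritParams q_sample
#' @param rng_seed Integer seed; the draw is reproducible and the caller's
#'   RNG state is untouched.
#' @export
q_sample_stepwise <- function(x0, t, s, rng_seed = NULL) {
  check_image(x0)
  t <- check_t(t, s)
  local_seed(rng_seed, {
    x <- x0
    for (i in seq_len(t)) {
      eps_i <- array(stats::rnorm(length(x)), dim = dim(x))
      x <- sqrt(1 - s$beta[i]) * x + sqrt(s$beta[i]) * eps_i
    }
    x
  })
}

#' Forward posterior q(x_t | x_{t+1}, x_0)
#'
#' Mean and variance of the Gaussian forward posterior (the distribution the
#' reverse process is trained to match). See [posterior_coefficients()] for
#' the closed form.
#'
#' @param x0 Clean image.
#' @param xt1 Sample at step `t + 1`, same shape as `x0`.
#' @param t Target step, `0 <= t <= T-1`.
#' @param s A `noise_schedule`.
#' @return List with `mean` (image) and `var` (scalar).
#' @export
q_posterior <- function(x0, xt1, t, s) {
  check_image(x0); check_image(xt1); check_same_shape(x0, xt1, "x0", "xt1")
  co <- posterior_coefficients(s, t)
  list(mean = co$coef_x0 * x0 + co$coef_xt1 * xt1, var = co$var)
}

#' Reverse-process mean from a noise prediction
#'
#' Parameterizes the reverse mean by the predicted noise:
#' \deqn{\mu_\theta = \frac{1}{\sqrt{\alpha_t}}\left(x_t -
#'   \frac{\beta_t}{\sqrt{1-\bar\alpha_t}}\,\hat\epsilon\right).}
#'
#' @param xt Noised image at step `t`.
#' @param eps_hat Predicted noise, same shape.
#' @param t Timestep in `1..T`.
#' @param s A `noise_schedule`.
#' @export
mu_theta_from_eps <- function(xt, eps_hat, t, s) {
  check_image(xt); check_image(eps_hat); check_same_shape(xt, eps_hat, "xt", "eps_hat")
  t <- check_t(t, s)
  (xt - s$beta[t] / sqrt(1 - s$alpha_bar[t]) * eps_hat) / sqrt(s$alpha[t])
}

#' Implied clean image from a noise prediction
#'
#' Inverts the closed-form marginal:
#' \eqn{\hat x_0 = (x_t - \sqrt{1-\bar\alpha_t}\,\hat\epsilon)/\sqrt{\bar\alpha_t}}.
#'
#' @inheritParams mu_theta_from_eps
#' @export
predicted_x0_from_eps <- function(xt, eps_hat, t, s) {
  t <- check_t(t, s)
  ab <- s$alpha_bar[t]
  (xt - sqrt(1 - ab) * eps_hat) / sqrt(ab)
}

#' One ancestral sampling step of the reverse process
#'
#' Draws \eqn{x_{t-1} = \mu_\theta(x_t, y, t) + \sigma_t z} with
#' \eqn{z \sim N(0, I)}, except at `t = 1` where `z = 0` by default so that
#' the final output is the reverse mean (standard DDPM practice; set
#' `noise_at_t1 = TRUE` for the literal rule at every step).
#'
#' @param xt Current sample at step `t`.
#' @param y Condition image, same spatial shape as `xt`.
#' @param t Timestep in `1..T`.
#' @param model A noise predictor (see [build_reference_unet()]).
#' @param s A `noise_schedule`; its `sigma_mode` fixes \eqn{\sigma_t}.
#' @param rng_seed Optional integer seed for `z`.
#' @param noise_at_t1 Add noise even at the final step? Default `FALSE`.
#' @return List with `mean`, `sample` and `predicted_x0` images.
#' @export
p_sample_step <- function(xt, y, t, model, s, rng_seed = NULL,
                          noise_at_t1 = FALSE) {
  check_image(xt); check_image(y)
  t <- check_t(t, s)
  eps_hat <- predict_noise(model, xt, y, t)
  if (!identical(dim(eps_hat), dim(xt)))
    stop(sprintf("noise predictor '%s' returned shape %s, expected %s",
                 model_fingerprint(model),
                 paste(dim(eps_hat), collapse = "x"),
                 paste(dim(xt), collapse = "x")))
  mean_ <- mu_theta_from_eps(xt, eps_hat, t, s)
  sig <- sqrt(s$sigma2[t])
  add_noise <- sig > 0 && (t > 1L || noise_at_t1)
  sample_ <- if (add_noise) {
    z <- local_seed(rng_seed, array(stats::rnorm(length(xt)), dim = dim(xt)))
    mean_ + sig * z
  } else mean_
  list(mean = mean_, sample = sample_,
       predicted_x0 = predicted_x0_from_eps(xt, eps_hat, t, s))
}

#' Full ancestral sampling loop
#'
#' Starts from pure noise \eqn{x_T \sim N(0, I)} and iterates the reverse
#' step for `t = T..1` given the condition `y`. Intermediate samples are not
#' clipped; the returned \eqn{x_0} is clipped to \[-1, 1\].
#'
#' @param y Condition image in \[-1, 1\] (matrix, or H x W x N array to
#'   sample a batch under one loop).
#' @param model A noise predictor.
#' @param s A `noise_schedule`.
#' @param rng_seed Integer seed; the whole trajectory is reproducible.
#' @param keep_trajectory If `TRUE`, also return the list of all `T + 1`
#'   states from `x_T` down to `x_0`.
#' @param noise_at_t1 Passed to [p_sample_step()].
#' @return The sampled image (same shape as `y`); with `keep_trajectory`,
#'   a list with elements `x0` and `trajectory`.
#' @export
p_sample_loop <- function(y, model, s, rng_seed = NULL,
                          keep_trajectory = FALSE, noise_at_t1 = FALSE) {
  check_image(y)
  local_seed(rng_seed, {
    x <- array(stats::rnorm(length(y)), dim = dim(y))
    traj <- if (keep_trajectory) vector("list", s$T + 1L) else NULL
    if (keep_trajectory) traj[[1L]] <- x
    for (t in seq(s$T, 1L)) {
      step <- tryCatch(
        p_sample_step(x, y, t, model, s, rng_seed = NULL,
                      noise_at_t1 = noise_at_t1),
        error = function(e) stop(sprintf(
          "reverse process failed at timestep t=%d: %s", t,
          conditionMessage(e)), call. = FALSE))
      x <- step$sample
      if (!all(is.finite(x)))
        stop(sprintf("non-finite values in reverse process at timestep t=%d", t))
      if (keep_trajectory) traj[[s$T - t + 2L]] <- x
    }
    x0 <- pmin(pmax(x, -1), 1)
    if (keep_trajectory) list(x0 = x0, trajectory = traj) else x0
  })
}
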
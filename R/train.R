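# Training loop for the noise predictor: Adam on the simplified
# epsilon-prediction objective, with uniformly drawn timesteps.

#' Training configuration
#'
#' Defaults are the full-scale settings of the underlying method
#' (2e5 iterations, learning rate 1e-4, 128x128 images, T = 2000,
#' beta from 1e-4 to 0.02); see [toy_train_config()] for a CPU-sized
#' profile used in tests.
#'
#' @param iterations Number of gradient steps.
#' @param learning_rate Adam learning rate.
#' @param batch_size Examples per step.
#' @param image_size Image side length.
#' @param seed RNG seed controlling batch order, timesteps and noise.
#' @param T_steps,beta_start,beta_end Forwarded to [linear_beta_schedule()].
#' @param base_channels,channel_mults Forwarded to [build_reference_unet()].
#' @param grad_clip Optional global gradient-norm clip (NULL = off).
#' @param log_file Optional path; per-iteration diagnostics are appended as
#'   JSON lines `{iter, loss, t_mean, lr}`.
#' @export
train_config <- function(iterations = 2e5, learning_rate = 1e-4,
                         batch_size = 8L, image_size = 128L, seed = 1L,
                         T_steps = 2000L, beta_start = 1e-4, beta_end = 0.02,
                         base_channels = 64L, channel_mults = c(1, 2, 4),
                         grad_clip = NULL, log_file = NULL) {
  stopifnot(iterations >= 1, learning_rate > 0, batch_size >= 1,
            image_size >= 8)
  structure(list(iterations = as.integer(iterations),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 image_size = as.integer(image_size), seed = as.integer(seed),
                 T_steps = as.integer(T_steps), beta_start = beta_start,
                 beta_end = beta_end, base_channels = as.integer(base_channels),
                 channel_mults = channel_mults, grad_clip = grad_clip,
                 log_file = log_file),
            class = "train_config")
}

#' Toy training profile for CPU-scale runs
#'
#' 16x16 images, T = 200, base width 16, 2000 iterations, batch 8 — sized so
#' a full train-and-sample run per task completes in minutes on one CPU.
#' The learning rate is raised to 2e-3, appropriate for the small network
#' and short schedule.
#'
#' @param ... Overrides passed to [train_config()].
#' @export
toy_train_config <- function(...) {
  defaults <- list(iterations = 2000L, learning_rate = 2e-3, batch_size = 8L,
                   image_size = 16L, T_steps = 200L, base_channels = 16L,
                   channel_mults = c(1, 2))
  args <- utils::modifyList(defaults, list(...))
  do.call(train_config, args)
}

adam_init <- function(params) {
  zeros <- function(p) {
    if (is.list(p)) lapply(p, zeros) else p * 0
  }
  list(m = zeros(params), v = zeros(params), step = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$step <- state$step + 1L
  state$m <- map_params2(function(m, g) beta1 * m + (1 - beta1) * g,
                         state$m, grads)
  state$v <- map_params2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                         state$v, grads)
  bc1 <- 1 - beta1^state$step
  bc2 <- 1 - beta2^state$step
  upd <- map_params2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                     state$m, state$v)
  params <- map_params2(`-`, params, upd)
  list(params = params, state = state)
}

grad_norm <- function(grads) {
  sqrt(sum(vapply(flatten_params(grads),
                  function(g) sum(as.vector(g)^2), numeric(1))))
}

#' Train a noise predictor on paired data
#'
#' Per iteration: draw a batch of `(x0, y)` pairs, an independent timestep
#' `t ~ U{1..T}` and noise field `eps ~ N(0, I)` per example, form
#' `x_t` by the closed-form marginal, and take an Adam step on the
#' per-pixel mean-squared error between `eps` and the model's prediction.
#' Fully reproducible from `cfg$seed`.
#'
#' @param model A `ref_unet` from [build_reference_unet()].
#' @param dataset Non-empty list of condition pairs (see
#'   [make_task_dataset()]), all images in \[-1, 1\].
#' @param cfg A [train_config()].
#' @param s A `noise_schedule`.
#' @return List with `model` (trained) and `history` (loss per iteration).
#' @export
train_diffusion <- function(model, dataset, cfg, s) {
  if (!inherits(model, "ref_unet")) stop("`model` must be a ref_unet")
  if (length(dataset) == 0L) stop("`dataset` is empty")
  H <- model$arch$image_size
  HW <- H * H
  B <- cfg$batch_size
  x0s <- vapply(dataset, function(p) as.vector(p$x0), numeric(HW))
  ys <- vapply(dataset, function(p) as.vector(p$y), numeric(HW))
  params <- model$params
  arch <- model$arch
  ad <- adam_init(params)
  history <- numeric(cfg$iterations)
  logc <- NULL
  if (!is.null(cfg$log_file)) {
    logc <- file(cfg$log_file, "a")
    on.exit(close(logc), add = TRUE)
  }
  local_seed(cfg$seed, {
    for (it in seq_len(cfg$iterations)) {
      idx <- sample.int(ncol(x0s), B, replace = TRUE)
      tt <- sample.int(s$T, B, replace = TRUE)
      x0 <- x0s[, idx, drop = FALSE]                      # HW x B
      y <- ys[, idx, drop = FALSE]
      eps <- matrix(stats::rnorm(HW * B), HW, B)
      sa <- sqrt(s$alpha_bar[tt])
      sn <- sqrt(1 - s$alpha_bar[tt])
      xt <- sweep(x0, 2, sa, "*") + sweep(eps, 2, sn, "*")
      fw <- unet_fwd(params, arch, matrix(as.vector(xt), ncol = 1L),
                     matrix(as.vector(y), ncol = 1L), tt, B)
      resid <- fw$out - as.vector(eps)
      loss <- mean(resid^2)
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at iteration %d", it))
      history[it] <- loss
      if (!is.null(logc))
        writeLines(sprintf(
          '{"iter": %d, "loss": %.8g, "t_mean": %.4g, "lr": %g}',
          it, loss, mean(tt), cfg$learning_rate), logc)
      dOut <- matrix(2 * resid / length(resid), ncol = 1L)
      grads <- unet_bwd(params, arch, fw, dOut)
      if (!is.null(cfg$grad_clip)) {
        gn <- grad_norm(grads)
        if (gn > cfg$grad_clip) {
          sc <- cfg$grad_clip / gn
          grads <- map_params2(function(g, ...) g * sc, grads, grads)
        }
      }
      st <- adam_step(params, grads, ad, cfg$learning_rate)
      params <- st$params
      ad <- st$state
    }
  })
  model$params <- params
  list(model = model, history = history)
}

schedule_fingerprint <- function(s) {
  list(T = s$T, beta_start = s$beta_start, beta_end = s$beta_end,
       sigma_mode = s$sigma_mode)
}

#' Save a model checkpoint
#'
#' Stores weights, architecture, the training configuration and a schedule
#' fingerprint. [load_checkpoint()] restores the model;
#' sampling entry points refuse a checkpoint whose schedule fingerprint
#' disagrees with the schedule in use.
#'
#' @param model A `ref_unet`.
#' @param path Destination file (RDS).
#' @param cfg Optional [train_config()].
#' @param s Optional `noise_schedule` whose fingerprint to record.
#' @export
save_checkpoint <- function(model, path, cfg = NULL, s = NULL) {
  saveRDS(list(params = model$params, arch = model$arch, train_config = cfg,
               schedule_fingerprint = if (!is.null(s)) schedule_fingerprint(s)),
          path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path File written by [save_checkpoint()].
#' @return List with `model`, `train_config`, `schedule_fingerprint`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- structure(list(params = ck$params, arch = ck$arch),
                     class = c("ref_unet", "noise_predictor"))
  list(model = model, train_config = ck$train_config,
       schedule_fingerprint = ck$schedule_fingerprint)
}

check_schedule_match <- function(fp, s) {
  if (is.null(fp)) return(invisible(TRUE))
  now <- schedule_fingerprint(s)
  if (!identical(fp[c("T", "beta_start", "beta_end")],
                 now[c("T", "beta_start", "beta_end")]))
    stop("checkpoint was trained under a different noise schedule; refusing to sample")
  invisible(TRUE)
}
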
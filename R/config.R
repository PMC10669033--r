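# Run configuration: one serializable object describing a full experiment.
# The schedule is stored as {T, beta_start, beta_end, sigma_mode}, never as
# raw per-step arrays.

#' Build a run configuration
#'
#' Defaults encode the full-scale settings of the method (T = 2000, beta
#' linear 1e-4..0.02, sigma_t^2 = beta_t, 128x128 images, 2e5 iterations at
#' learning rate 1e-4); pass `profile = "toy"` for the CPU-sized profile
#' used throughout the tests.
#'
#' @param task `"SR"`, `"DENOISE"` or `"INPAINT"`.
#' @param profile `"full"` or `"toy"`.
#' @param schedule,model,train,task_params,data Named lists overriding
#'   individual fields of the corresponding blocks.
#' @param seed Global seed.
#' @param output_dir Where [run_experiment()] writes artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(task = c("SR", "DENOISE", "INPAINT"),
                       profile = c("toy", "full"), schedule = list(),
                       model = list(), train = list(), task_params = list(),
                       data = list(), seed = 1L, output_dir = tempfile("run")) {
  task <- match.arg(task)
  profile <- match.arg(profile)
  base <- if (profile == "full") {
    list(schedule = list(T = 2000L, beta_start = 1e-4, beta_end = 0.02,
                         sigma_mode = "beta"),
         model = list(image_size = 128L, base_channels = 64L,
                      channel_mults = c(1, 2, 4), num_groups = 8L),
         train = list(iterations = 2e5, learning_rate = 1e-4,
                      batch_size = 8L),
         data = list(style = "PROSTATE_T2", n_images = 500L,
                     texture_strength = 0.05))
  } else {
    list(schedule = list(T = 200L, beta_start = 1e-4, beta_end = 0.02,
                         sigma_mode = "beta"),
         model = list(image_size = 16L, base_channels = 16L,
                      channel_mults = c(1, 2), num_groups = 8L),
         train = list(iterations = 2000L, learning_rate = 2e-3,
                      batch_size = 8L),
         data = list(style = "PROSTATE_T2", n_images = 200L,
                     texture_strength = 0.05))
  }
  tp_default <- switch(task,
    SR = list(factor = 4),
    DENOISE = list(gauss_sigma = 0.1, sp_amount = 0.05),
    INPAINT = list(mask_kind = "rectangles", mask_count = c(1L, 3L),
                   mask_size = c(0.15, 0.35)))
  cfg <- list(
    task = task, profile = profile,
    schedule = utils::modifyList(base$schedule, schedule),
    model = utils::modifyList(base$model, model),
    train = utils::modifyList(base$train, train),
    task_params = utils::modifyList(tp_default, task_params),
    data = utils::modifyList(base$data, data),
    seed = as.integer(seed), output_dir = output_dir)
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML (JSON fallback)
#' @param cfg A `run_config`.
#' @param path Destination; extension `.yaml`/`.yml` or `.json`.
#' @export
write_run_config <- function(cfg, path) {
  x <- unclass(cfg)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#' @param path File written by [write_run_config()] (or hand-authored).
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- do.call(run_config, c(
    list(task = x$task, profile = x$profile %||% "toy",
         schedule = x$schedule %||% list(), model = x$model %||% list(),
         train = x$train %||% list(),
         task_params = x$task_params %||% list(),
         data = x$data %||% list(), seed = x$seed %||% 1L),
    if (!is.null(x$output_dir)) list(output_dir = x$output_dir)))
  cfg
}

config_schedule <- function(cfg) {
  linear_beta_schedule(cfg$schedule$T, cfg$schedule$beta_start,
                       cfg$schedule$beta_end, cfg$schedule$sigma_mode)
}
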
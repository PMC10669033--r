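# End-to-end experiment orchestration: data -> train -> sample -> evaluate,
# with self-describing output directories.

#' Run a full experiment from a configuration
#'
#' Generates the synthetic dataset, trains the noise predictor, samples the
#' test split under one ancestral loop, evaluates, and writes artifacts to
#' `cfg$output_dir`: `checkpoint.rds`, `samples/*.png`, `report.json`,
#' `config.yaml` (the resolved configuration) and `log.jsonl`. Idempotent
#' given the seed; any stage failure leaves partial outputs plus a `FAILED`
#' marker file containing the error message.
#'
#' @param cfg A [run_config()].
#' @return The report list, invisibly.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out, "log.jsonl")
  log_line <- function(...) {
    cat(jsonlite::toJSON(list(time = format(Sys.time()), ...),
                         auto_unbox = TRUE), "\n",
        file = logf, append = TRUE)
  }
  result <- tryCatch({
    write_run_config(cfg, file.path(out, "config.yaml"))
    s <- config_schedule(cfg)
    pspec <- phantom_spec(image_size = cfg$model$image_size,
                          style = cfg$data$style,
                          n_images = cfg$data$n_images, seed = cfg$seed,
                          texture_strength = cfg$data$texture_strength)
    tp <- cfg$task_params
    if (cfg$task == "INPAINT") {
      tp <- list(spec = mask_spec(kind = tp$mask_kind, count = tp$mask_count,
                                  size = tp$mask_size, seed = cfg$seed))
    }
    ds <- make_task_dataset(pspec, cfg$task, tp)
    log_line(stage = "data", train = length(ds$train), val = length(ds$val),
             test = length(ds$test))
    tcfg <- train_config(iterations = cfg$train$iterations,
                         learning_rate = cfg$train$learning_rate,
                         batch_size = cfg$train$batch_size,
                         image_size = cfg$model$image_size, seed = cfg$seed,
                         T_steps = cfg$schedule$T,
                         beta_start = cfg$schedule$beta_start,
                         beta_end = cfg$schedule$beta_end,
                         base_channels = cfg$model$base_channels,
                         channel_mults = cfg$model$channel_mults)
    net <- build_reference_unet(cfg$model$image_size,
                                base_channels = cfg$model$base_channels,
                                channel_mults = cfg$model$channel_mults,
                                num_groups = cfg$model$num_groups,
                                seed = cfg$seed)
    tr <- train_diffusion(net, ds$train, tcfg, s)
    log_line(stage = "train", iterations = tcfg$iterations,
             loss_first = mean(utils::head(tr$history, 100)),
             loss_last = mean(utils::tail(tr$history, 100)))
    save_checkpoint(tr$model, file.path(out, "checkpoint.rds"), tcfg, s)
    nt <- length(ds$test)
    yb <- simplify2array(lapply(ds$test, function(p) p$y))
    x0b <- simplify2array(lapply(ds$test, function(p) p$x0))
    if (nt == 1L) {
      dim(yb) <- c(dim(yb), 1L)
      dim(x0b) <- c(dim(x0b), 1L)
    }
    smp <- p_sample_loop(yb, tr$model, s,
                         rng_seed = derive_seed(cfg$seed, 999L))
    sdir <- file.path(out, "samples")
    dir.create(sdir, showWarnings = FALSE)
    for (i in seq_len(nt))
      write_image(smp[, , i], file.path(sdir, sprintf("sample_%03d.png", i)))
    per <- lapply(seq_len(nt), function(i) {
      r <- list(
        psnr_sample = as.numeric(psnr(x0b[, , i], smp[, , i])),
        psnr_condition = as.numeric(psnr(x0b[, , i], yb[, , i])),
        accutance_sample = accutance(smp[, , i]),
        accutance_condition = accutance(yb[, , i]),
        accutance_ref = accutance(x0b[, , i]))
      if (cfg$task == "INPAINT") {
        m <- ds$test[[i]]$mask
        r$masked_mse_sample <- mean((smp[, , i][m] - x0b[, , i][m])^2)
        r$masked_mse_fill <- mean((0 - x0b[, , i][m])^2)
      }
      r
    })
    agg <- function(field) mean(vapply(per, `[[`, numeric(1), field))
    report <- list(
      task = cfg$task, n = nt, seed = cfg$seed,
      loss_first100 = mean(utils::head(tr$history, 100)),
      loss_last100 = mean(utils::tail(tr$history, 100)),
      psnr_sample = agg("psnr_sample"),
      psnr_condition = agg("psnr_condition"),
      accutance_sample = agg("accutance_sample"),
      accutance_condition = agg("accutance_condition"),
      accutance_ref = agg("accutance_ref"))
    if (cfg$task == "INPAINT") {
      report$masked_mse_sample <- agg("masked_mse_sample")
      report$masked_mse_fill <- agg("masked_mse_fill")
    }
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    log_line(stage = "done")
    report
  }, error = function(e) {
    writeLines(conditionMessage(e), file.path(out, "FAILED"))
    log_line(stage = "error", message = conditionMessage(e))
    stop(e)
  })
  invisible(result)
}
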
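# cddpm — conditional denoising diffusion for medical image-to-image tasks

`cddpm` is an R implementation of conditional denoising diffusion
probabilistic models (cDDPMs) for paired image-to-image generation in
medical imaging: **super-resolution**, **denoising**, and **inpainting** of
grayscale images. It is aimed at researchers who want a transparent,
fully-testable reference for the probabilistic machinery of conditional
diffusion — every formula is implemented explicitly and checked against
independent oracles — rather than a GPU-scale production trainer.

## The model

A fixed forward Markov chain corrupts the target image x₀ with Gaussian
noise over T steps, q(xₜ | xₜ₋₁) = N(√(1−βₜ) xₜ₋₁, βₜ I), with βₜ linearly
increasing from 1e-4 to 0.02 (T = 2000 at full scale). Its closed-form
marginal xₜ = √ᾱₜ x₀ + √(1−ᾱₜ) ε (ᾱₜ = ∏ᵢ≤ₜ(1−βᵢ)) drives training: a
conditional noise predictor ε_θ(xₜ, y, t) — a small U-Net with group
normalization and sinusoidal time embeddings, given the degraded condition
image y as a second input channel — is fit by Adam on the simplified
objective ‖ε − ε_θ‖². Sampling is ancestral, from pure noise down to x₀:

    x_{t−1} = (1/√αₜ) (xₜ − βₜ/√(1−ᾱₜ) · ε_θ(xₜ, y, t)) + σₜ z,  σₜ² = βₜ.

The package also implements the full variational bound as diagnostics:
per-term Gaussian KLs, the prior term L_T, and the discretized Gaussian
decoder L₀ over 8-bit quantization bins. A synthetic phantom generator
(nested-zone prostate-like, chest-X-ray-like, low-contrast soft-tissue
styles) makes every pipeline runnable with no external data.

## Worked example

```r
library(cddpm)

# the full-scale noise schedule
s <- linear_beta_schedule(2000)
s
#> <noise_schedule> T=2000, beta in [0.0001, 0.02], sigma_mode=beta, alpha_bar[T]=1.629e-09

# a synthetic denoising dataset: 200 prostate-like phantoms, 16x16,
# Gaussian noise (sd 0.1) + 5% salt-and-pepper on the conditions
spec <- phantom_spec(image_size = 16, n_images = 200, seed = 11)
ds   <- make_task_dataset(spec, "DENOISE")
pair <- ds$test[[1]]
sprintf("condition PSNR vs target: %.2f dB", psnr(pair$x0, pair$y))
#> "condition PSNR vs target: 17.39 dB"

# train the toy profile (T = 200, 2000 iterations, ~4 min on 1 CPU)
cfg <- toy_train_config(seed = 5)
st  <- linear_beta_schedule(cfg$T_steps, cfg$beta_start, cfg$beta_end)
net <- build_reference_unet(16, base_channels = cfg$base_channels,
                            channel_mults = cfg$channel_mults, seed = cfg$seed)
tr  <- train_diffusion(net, ds$train, cfg, st)

# sample the test split and compare to the degraded condition
yb  <- simplify2array(lapply(ds$test, `[[`, "y"))
x0b <- simplify2array(lapply(ds$test, `[[`, "x0"))
smp <- p_sample_loop(yb, tr$model, st, rng_seed = 77)
mean(sapply(seq_len(dim(smp)[3]), function(i) psnr(x0b[,,i], smp[,,i])))
#> 24.85   # diffusion samples
mean(sapply(seq_len(dim(smp)[3]), function(i) psnr(x0b[,,i], yb[,,i])))
#> 16.87   # noisy conditions
```

The samples recover ~8 dB over the noisy conditions — the model has learned
to denoise, at desk scale, via the generative reverse process. The same
pipeline is available in one call (`run_experiment(run_config("DENOISE"))`)
and from the shell:

```sh
Rscript -e 'cddpm::run_cli()' run --config cfg.yaml --out outdir
Rscript -e 'cddpm::run_cli()' synth --style prostate_t2 --n 100 --size 64 --seed 7 --out phantoms/
```

## Layout

- `R/schedules.R`, `R/diffusion.R` — noise schedule; forward process,
  forward posterior, reverse step, ancestral sampling
- `R/losses.R` — simplified loss, Gaussian KL, variational-bound terms,
  discretized decoder
- `R/nn.R`, `R/unet.R`, `R/train.R`, `src/conv3.cpp` — reference U-Net with
  hand-derived backprop (finite-difference-verified), Adam loop, checkpoints
- `R/conditioning.R`, `R/phantoms.R` — task condition constructors,
  phantom generator
- `R/metrics.R`, `R/io.R`, `R/config.R`, `R/experiment.R`, `R/cli.R` —
  metrics, PNG/NIfTI I/O, run configs, orchestration, CLI

See `vignettes/conditional-diffusion-methods.Rmd` for the model, the design
decisions and their rationale, and known limitations.
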
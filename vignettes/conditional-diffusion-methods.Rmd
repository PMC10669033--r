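---
title: "Conditional denoising diffusion for medical image-to-image tasks: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional denoising diffusion for medical image-to-image tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`cddpm` implements a conditional denoising diffusion probabilistic model
(cDDPM) for paired image-to-image generation. The target image $x_0$ and a
correlated condition image $y$ (a degraded version of $x_0$) live on the
$[-1, 1]$ intensity scale. A fixed forward Markov chain corrupts $x_0$ with
Gaussian noise over $T$ steps,

$$q(x_t \mid x_{t-1}) = N\!\left(\sqrt{1-\beta_t}\,x_{t-1},\ \beta_t I\right),$$

with variances $\beta_t$ linearly increasing from $10^{-4}$ to $0.02$ over
$T = 2000$ steps in the full-scale profile. Writing
$\alpha_t = 1 - \beta_t$ and $\bar\alpha_t = \prod_{i\le t}\alpha_i$, the
chain admits the closed-form marginal
$x_t = \sqrt{\bar\alpha_t}x_0 + \sqrt{1-\bar\alpha_t}\,\epsilon$, which is
what training actually samples. The learned reverse process is a chain of
Gaussians $p_\theta(x_{t-1} \mid x_t, y) = N(\mu_\theta(x_t, y, t), \sigma_t^2 I)$
whose mean is parameterized through a noise predictor
$\epsilon_\theta$:

$$\mu_\theta = \tfrac{1}{\sqrt{\alpha_t}}\left(x_t -
  \tfrac{\beta_t}{\sqrt{1-\bar\alpha_t}}\,\epsilon_\theta(x_t, y, t)\right),
  \qquad \sigma_t^2 = \beta_t .$$

Training minimizes the simplified objective
$\lVert\epsilon - \epsilon_\theta(\sqrt{\bar\alpha_t}x_0 +
\sqrt{1-\bar\alpha_t}\epsilon, y, t)\rVert^2$ with $t \sim U\{1..T\}$ and
$\epsilon \sim N(0, I)$; the full variational bound — per-term Gaussian KLs
plus a discretized Gaussian decoder for 8-bit data — is implemented as a
diagnostic only (`vlb_term()`, `lT_term()`, `l0_term()`). Sampling is
ancestral: start at $x_T \sim N(0, I)$ and iterate
$x_{t-1} = \mu_\theta + \sigma_t z$ down to $x_0$.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `T` | 2000 (toy: 200) | diffusion steps; longer schedules push $\bar\alpha_T \to 0$ so the prior assumption $x_T \sim N(0,I)$ holds ($\bar\alpha_{2000} \approx 1.6\times10^{-9}$) |
| `beta_start`, `beta_end` | $10^{-4}$, $0.02$ | endpoints of the linear variance schedule, on the $[-1,1]$ intensity scale |
| `sigma_mode` | `"beta"` | sampling variance $\sigma_t^2$; `"beta_tilde"` uses the forward-posterior variance, `"zero"` gives the deterministic mean path (tests) |
| `learning_rate` | $10^{-4}$ (toy: $2\times10^{-3}$) | Adam step size; the toy network is tiny and short-lived, so a larger step is appropriate |
| `iterations` | $2\times10^5$ (toy: 2000) | gradient steps |
| `image_size` | 128 (toy: 16) | square side length |
| `delta` in `l0_term()` | $1/255$ | half-width of an 8-bit quantization bin mapped to $[-1,1]$; makes $L_0$ a proper discretized likelihood |

## Numerical and design choices

Decisions the underlying method leaves open, and how this package resolves
them:

* **Final-step noise.** The ancestral rule adds $\sigma_t z$ at every step;
  we set $z = 0$ at $t = 1$ (standard DDPM practice — noise added while
  *producing* $x_0$ only degrades the output and contradicts the decoder
  term). `noise_at_t1 = TRUE` restores the literal rule.
* **Clipping.** Intermediate $x_t$ are left unclipped, preserving the
  Gaussian assumptions of every step; only the final $x_0$ is clipped to
  $[-1, 1]$.
* **Conditioning mechanism.** How $y$ enters $\epsilon_\theta$ is not
  specified by the method; the reference network concatenates $y$ with
  $x_t$ as a second input channel (the standard choice for conditional
  DDPMs). Any object implementing `predict_noise()` can be substituted.
* **Decoder edge bins.** The saturating integration-limit function clamps
  bin edges to $\pm1$, so the 256 bin masses do not sum to one. Both
  conventions are implemented: `"literal"` (faithful) and `"open"` (edge
  bins extend to infinity; normalized; the default). CDF differences are
  evaluated in log space and remain finite down to $\sigma \sim 10^{-4}$.
* **Loss reduction.** The squared norm is reduced as a per-pixel mean so
  loss magnitudes are resolution-independent; this rescales the gradient
  only.
* **Decoder variance.** $L_0$ uses $\sigma_1^2 = \beta_1$, consistent with
  $\sigma_t^2 = \beta_t$; the bound's $t$-independent constant is never
  needed explicitly, and the mean-space and noise-space forms of $L_t$ are
  verified to differ by a model-independent constant only.
* **Optimizer and embedding.** Adam (only the learning rate is prescribed),
  sinusoidal time embedding of dimension `4 * base_channels`, group
  normalization, zero-initialized output convolution. No EMA, no
  augmentation, no gradient clipping by default (`grad_clip` is available).
* **Oracle round trips.** A "cheating" predictor useful for validating the
  sampler must return the noise consistent with the *current* state,
  $(x_t - \sqrt{\bar\alpha_t}x_0)/\sqrt{1-\bar\alpha_t}$; replaying one
  fixed forward draw diverges under the deterministic reverse recursion
  (its noise coefficient is amplified by $1/\sqrt{\bar\alpha_T}$).

The reference U-Net itself (depth, widths, block layout) is this package's
construction — the method prescribes only "a U-Net with group
normalization". Everything is written in R with one compiled kernel (the
3×3 convolution, via RcppArmadillo); gradients of every layer are
hand-derived and checked against finite differences in the test suite.

## The synthetic world

The clinical datasets behind the method (prostate T2 MRI with zonal
annotations, chest X-rays, prostate T1 SPGR MRI) are private or external.
`generate_phantoms()` emulates their *structure* at configurable size:

* `PROSTATE_T2` — body ellipse containing a peripheral-zone ellipse with a
  nested transition-zone core; mean intensities ordered TZ > PZ >
  background with margins ≥ 0.2; a zone label map accompanies each image.
* `CHEST_XRAY` — bright lung-field ellipses with rib-like periodic bands on
  a vertical-gradient background.
* `PROSTATE_T1` — a single low-contrast soft-tissue ellipse.

All styles add band-limited Gaussian texture (`texture_strength`, default
0.05 — visible but subordinate to the anatomy) and are bit-reproducible
per `(seed, index)`. Task degradations mirror the applications:
box-downsample + bilinear-upsample for super-resolution, with the factor
interpreted per axis; the canonical factor ladder is geometric with ratio
$\sqrt2$ ($2\sqrt2, 4, 4\sqrt2, 8, 8\sqrt2, 16$), and irrational factors
are handled by rounding the intermediate size, though any real factor
$\ge 1$ is accepted; Gaussian noise (sd 0.1) plus 5 %
salt-and-pepper for denoising — magnitudes the method leaves unspecified,
chosen here as clearly visible but recoverable corruption; random
rectangle/ellipse masks filled with mid-gray for inpainting, drawn fresh
per training example and frozen per index at test time. The 80/10/10
index split mirrors the patient-wise split ratio of the original data
(238/29/29).

What phantoms do **not** emulate: MRI noise statistics (Rician), k-space
acquisition, scanner artifacts, anatomical variability beyond ellipse
jitter. A green end-to-end test therefore establishes that the
probabilistic machinery, conditioning and optimizer work as specified — not
that clinical-grade image quality is reachable, which requires the original
data and GPU-scale training ($2\times10^5$ iterations at $128\times128$).

## Scaled-down acceptance runs

The test suite trains the toy profile (16×16 phantoms, $T = 200$, 2000
iterations, batch 8, ~200 s per task on one CPU) on each task and checks
that (a) the loss decreases, (b) samples beat the condition — higher PSNR
against $x_0$ for super-resolution and denoising, lower masked-region MSE
than the mid-gray fill for inpainting — over 20 test pairs, and (c) reports
reproduce bit-identically under a fixed seed (verified on a further-reduced
configuration purely to stay inside the CI time budget; the code path is
identical). Representative numbers from these runs: denoising
PSNR ≈ 24.9 dB versus 16.9 dB for the condition; super-resolution ≈ 22.8 dB
versus 20.6 dB.

## Known limitations

* Accutance has no published formula in this context; here it is the mean
  3×3 Sobel gradient magnitude over interior pixels. Absolute values are
  not comparable across implementations.
* Perceptual metrics (LPIPS, FID) need pretrained networks and are out of
  scope; `evaluate_pairs()` covers PSNR and accutance, `dice()` covers
  overlap.
* Single-channel 2-D grayscale only; no DDIM-style accelerated sampling,
  no classifier(-free) guidance, no learned variances.
* NIfTI support is read-only (a minimal NIfTI-1 parser); outputs are 8-bit
  PNG.
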
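# Anatomy-like phantom generator. Piecewise-smooth ellipse phantoms stand in
# for the private/external clinical datasets so that every task pipeline is
# exercisable without any download. Three styles emulate the structure the
# tasks need (nested prostate zones, rib-like bands, low-contrast soft
# tissue), not imaging physics.

#' Phantom generator specification
#'
#' @param image_size Side length of the square phantoms (>= 8).
#' @param style `"PROSTATE_T2"` (body ellipse with nested peripheral-zone
#'   ring and transition-zone core), `"CHEST_XRAY"` (bright lung-field
#'   ellipses with rib-like bands on a gradient background) or
#'   `"PROSTATE_T1"` (single low-contrast soft-tissue ellipse).
#' @param n_images Number of phantoms (>= 1).
#' @param seed Integer seed; phantoms are deterministic per `(seed, index)`.
#' @param texture_strength Standard deviation of the band-limited texture
#'   added to the piecewise-smooth component, on the \[-1, 1\] scale.
#'   Default 0.05.
#' @export
phantom_spec <- function(image_size = 64L,
                         style = c("PROSTATE_T2", "CHEST_XRAY", "PROSTATE_T1"),
                         n_images = 1L, seed = 1L, texture_strength = 0.05) {
  style <- match.arg(style)
  stopifnot(image_size >= 8, n_images >= 1, texture_strength >= 0)
  structure(list(image_size = as.integer(image_size), style = style,
                 n_images = as.integer(n_images), seed = as.integer(seed),
                 texture_strength = texture_strength),
            class = "phantom_spec")
}

# separable Gaussian blur with edge replication
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  blur1 <- function(m) {
    n <- nrow(m)
    pad <- rbind(m[rep(1L, r), , drop = FALSE], m,
                 m[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * pad[j:(j + n - 1L), , drop = FALSE]
    out
  }
  t(blur1(t(blur1(img))))
}

ellipse_mask <- function(H, W, cy, cx, ay, ax, theta = 0) {
  yy <- matrix(seq(-1, 1, length.out = H), H, W)
  xx <- matrix(seq(-1, 1, length.out = W), H, W, byrow = TRUE)
  u <- (yy - cy) * cos(theta) + (xx - cx) * sin(theta)
  v <- -(yy - cy) * sin(theta) + (xx - cx) * cos(theta)
  (u / ay)^2 + (v / ax)^2 <= 1
}

# smooth sinusoidal coordinate warp applied to a label-style painter:
# instead of warping pixels we jitter the ellipse parameters slightly and
# add a low-frequency radial perturbation through the texture field.
phantom_one <- function(spec, index) {
  H <- spec$image_size
  sd_seed <- derive_seed(spec$seed, index)
  local_seed(sd_seed, {
    zones <- NULL
    if (spec$style == "PROSTATE_T2") {
      img <- matrix(-0.85, H, H)
      th <- stats::runif(1, -0.4, 0.4)
      body <- ellipse_mask(H, H, stats::runif(1, -0.08, 0.08),
                           stats::runif(1, -0.08, 0.08),
                           stats::runif(1, 0.7, 0.85),
                           stats::runif(1, 0.75, 0.9), th)
      img[body] <- -0.35
      pcy <- stats::runif(1, -0.1, 0.1)
      pcx <- stats::runif(1, -0.1, 0.1)
      pay <- stats::runif(1, 0.38, 0.5)
      pax <- stats::runif(1, 0.42, 0.55)
      pz <- ellipse_mask(H, H, pcy, pcx, pay, pax, th)
      img[pz] <- 0.05
      fr <- stats::runif(1, 0.45, 0.6)
      ocy <- stats::runif(1, -0.1, 0.1) * (1 - fr) * pay
      ocx <- stats::runif(1, -0.1, 0.1) * (1 - fr) * pax
      tz <- ellipse_mask(H, H, pcy + ocy, pcx + ocx, fr * pay, fr * pax, th)
      img[tz] <- 0.5
      zones <- matrix(0L, H, H)
      zones[pz & !tz] <- 1L
      zones[tz] <- 2L
    } else if (spec$style == "CHEST_XRAY") {
      yy <- matrix(seq(-1, 1, length.out = H), H, H)
      img <- -0.4 - 0.25 * yy            # vertical gradient background
      th <- stats::runif(1, -0.15, 0.15)
      sep <- stats::runif(1, 0.35, 0.45)
      ay <- stats::runif(1, 0.5, 0.62)
      ax <- stats::runif(1, 0.24, 0.3)
      lungL <- ellipse_mask(H, H, stats::runif(1, -0.05, 0.1), -sep, ay, ax, th)
      lungR <- ellipse_mask(H, H, stats::runif(1, -0.05, 0.1), sep, ay, ax, -th)
      lungs <- lungL | lungR
      img[lungs] <- 0.25
      freq <- stats::runif(1, 3.5, 5)
      phase <- stats::runif(1, 0, 2 * pi)
      ribs <- 0.2 * sin(2 * pi * freq * yy + phase)
      img[lungs] <- img[lungs] + ribs[lungs]
    } else { # PROSTATE_T1
      img <- matrix(-0.5, H, H)
      body <- ellipse_mask(H, H, stats::runif(1, -0.08, 0.08),
                           stats::runif(1, -0.08, 0.08),
                           stats::runif(1, 0.55, 0.7),
                           stats::runif(1, 0.6, 0.75),
                           stats::runif(1, -0.4, 0.4))
      img[body] <- -0.2
    }
    img <- gaussian_blur(img, sigma = H / 64)   # soften region boundaries
    if (spec$texture_strength > 0) {
      tex <- gaussian_blur(matrix(stats::rnorm(H * H), H, H), sigma = 1.5)
      tex <- tex / stats::sd(tex) * spec$texture_strength
      img <- img + tex
    }
    list(image = clamp_unit(img), zones = zones)
  })
}

#' Generate a batch of phantom images
#'
#' Deterministic per `(spec$seed, index)`: the same spec always yields
#' bit-identical phantoms. `PROSTATE_T2` phantoms also carry a zone label
#' map (0 background, 1 peripheral zone, 2 transition zone); by
#' construction the transition zone lies strictly inside the peripheral
#' ellipse and the noise-free mean intensities are ordered
#' TZ > PZ > background with margins of at least 0.2.
#'
#' @param spec A [phantom_spec()].
#' @return List of `n_images` elements, each `list(image, zones)`.
#' @export
generate_phantoms <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  lapply(seq_len(spec$n_images), function(i) phantom_one(spec, i))
}

#' Build a train/val/test task dataset from phantoms
#'
#' Composes [generate_phantoms()] with the matching condition constructor
#' and splits by index 80/10/10 (mirroring a patient-wise split). Inpainting
#' masks are drawn per-index deterministically in the test and validation
#' splits, and randomly (from the per-index phantom seed stream) in the
#' training split.
#'
#' @param spec A [phantom_spec()].
#' @param task `"SR"`, `"DENOISE"` or `"INPAINT"`.
#' @param task_params List of parameters for the condition constructor:
#'   SR: `factor`; DENOISE: `gauss_sigma`, `sp_amount`; INPAINT: a
#'   [mask_spec()] as `spec` (its seed is re-derived per index).
#' @return List with `train`, `val`, `test`: lists of `condition_pair`s
#'   (each with the phantom's zone map in `meta$zones`).
#' @export
make_task_dataset <- function(spec, task = c("SR", "DENOISE", "INPAINT"),
                              task_params = list()) {
  task <- match.arg(task)
  ph <- generate_phantoms(spec)
  n <- length(ph)
  n_tr <- floor(0.8 * n)
  n_va <- floor(0.1 * n)
  split_of <- function(i) {
    if (i <= n_tr) "train" else if (i <= n_tr + n_va) "val" else "test"
  }
  pairs <- lapply(seq_len(n), function(i) {
    x0 <- ph[[i]]$image
    pseed <- derive_seed(spec$seed, 100000L + i)
    pair <- switch(task,
      SR = make_sr_condition(x0, task_params$factor %||% 4),
      DENOISE = make_noise_condition(
        x0, task_params$gauss_sigma %||% 0.1,
        task_params$sp_amount %||% 0.05, seed = pseed),
      INPAINT = {
        base_spec <- task_params$spec %||% mask_spec()
        ms <- base_spec
        ms$seed <- derive_seed(base_spec$seed, i)
        mode <- if (split_of(i) == "train") "train" else "test"
        if (mode == "train") local_seed(pseed,
          make_inpaint_condition(x0, ms, mode = "train"))
        else make_inpaint_condition(x0, ms, mode = "test")
      })
    pair$meta$zones <- ph[[i]]$zones
    pair$meta$index <- i
    pair
  })
  list(train = pairs[seq_len(n_tr)],
       val = if (n_va > 0) pairs[n_tr + seq_len(n_va)] else list(),
       test = pairs[setdiff(seq_len(n), seq_len(n_tr + n_va))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
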
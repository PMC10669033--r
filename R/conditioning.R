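# Construction of (x0, y) training pairs for the three tasks
# (super-resolution, denoising, inpainting) and intensity normalization.

#' Construct and validate a condition pair
#'
#' @param x0 Target image in \[-1, 1\].
#' @param y Condition image, same shape, in \[-1, 1\].
#' @param task One of `"SR"`, `"DENOISE"`, `"INPAINT"`.
#' @param mask Binary matrix (INPAINT only).
#' @param meta List of degradation parameters actually used.
#' @return An object of class `condition_pair`.
#' @export
condition_pair <- function(x0, y, task = c("SR", "DENOISE", "INPAINT"),
                           mask = NULL, meta = list()) {
  task <- match.arg(task)
  check_image(x0); check_image(y)
  check_same_shape(x0, y, "x0", "y")
  if (max(abs(x0)) > 1 + 1e-9 || max(abs(y)) > 1 + 1e-9)
    stop("x0 and y must lie in [-1, 1]")
  if (task == "INPAINT") {
    if (is.null(mask)) stop("INPAINT pairs need a mask")
    check_same_shape(x0, mask, "x0", "mask")
    if (any(y[!mask] != x0[!mask]))
      stop("INPAINT invariant violated: y must equal x0 outside the mask")
  }
  structure(list(x0 = x0, y = y, task = task, mask = mask, meta = meta),
            class = "condition_pair")
}

#' @export
print.condition_pair <- function(x, ...) {
  cat(sprintf("<condition_pair> task=%s, %dx%d%s\n", x$task, nrow(x$x0),
              ncol(x$x0),
              if (!is.null(x$mask))
                sprintf(", masked %.1f%%", 100 * mean(x$mask)) else ""))
  invisible(x)
}

#' Patient-wise intensity normalization to \[-1, 1\]
#'
#' Linearly maps a group of images sharing one patient/source to \[-1, 1\]
#' using the group's global minimum and maximum (so relative intensities
#' within the group are preserved). A constant group maps to all zeros.
#' The realized `(min, max)` is attached as attribute `"norm_range"` for
#' inversion with [denormalize_patientwise()].
#'
#' @param group Non-empty list of numeric matrices with finite values.
#' @return List of matrices in \[-1, 1\] with attribute `norm_range`.
#' @export
normalize_patientwise <- function(group) {
  if (length(group) == 0L) stop("empty group")
  vals <- unlist(lapply(group, as.vector))
  if (!all(is.finite(vals))) stop("non-finite intensities in group")
  lo <- min(vals)
  hi <- max(vals)
  out <- if (hi > lo) {
    lapply(group, function(m) 2 * (m - lo) / (hi - lo) - 1)
  } else {
    lapply(group, function(m) m * 0)
  }
  attr(out, "norm_range") <- c(min = lo, max = hi)
  out
}

#' Invert patient-wise normalization
#' @param group Output of [normalize_patientwise()] (or any image list).
#' @param range Length-2 vector `c(min, max)`; defaults to the stored
#'   `norm_range` attribute.
#' @export
denormalize_patientwise <- function(group, range = attr(group, "norm_range")) {
  if (is.null(range)) stop("no norm_range available")
  lo <- range[[1]]
  hi <- range[[2]]
  lapply(group, function(m) (m + 1) / 2 * (hi - lo) + lo)
}

# separable area-average resize: each output cell is the overlap-weighted
# mean of input cells (exact box filter for integer ratios)
area_weights <- function(n_in, n_out) {
  Wm <- matrix(0, n_out, n_in)
  r <- n_in / n_out
  for (i in seq_len(n_out)) {
    a <- (i - 1) * r
    b <- i * r
    j0 <- floor(a) + 1
    j1 <- ceiling(b)
    for (j in j0:min(j1, n_in)) {
      ov <- min(b, j) - max(a, j - 1)
      if (ov > 0) Wm[i, j] <- ov / r
    }
  }
  Wm
}

# separable bilinear resize with half-pixel centre alignment
bilinear_weights <- function(n_in, n_out) {
  Wm <- matrix(0, n_out, n_in)
  r <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * r - 0.5
    j0 <- floor(src)
    fr <- src - j0
    ja <- min(max(j0 + 1, 1), n_in)
    jb <- min(max(j0 + 2, 1), n_in)
    Wm[i, ja] <- Wm[i, ja] + (1 - fr)
    Wm[i, jb] <- Wm[i, jb] + fr
  }
  Wm
}

#' Resize by area (box) averaging
#' @param img Numeric matrix.
#' @param h,w Output dimensions.
#' @export
resize_area <- function(img, h, w = h) {
  area_weights(nrow(img), h) %*% img %*% t(area_weights(ncol(img), w))
}

#' Resize by bilinear interpolation
#' @param img Numeric matrix.
#' @param h,w Output dimensions.
#' @export
resize_bilinear <- function(img, h, w = h) {
  bilinear_weights(nrow(img), h) %*% img %*% t(bilinear_weights(ncol(img), w))
}

#' Super-resolution condition: downsample then upscale
#'
#' The condition is `y = upsample(downsample(x0, factor))`: box/area
#' averaging down to `round(side / factor)` pixels per axis (the factor is
#' per-axis), then bilinear interpolation back to the original size.
#' Non-integer factors (e.g. `2*sqrt(2)`) are supported through the rounded
#' intermediate size.
#'
#' @param x0 Target image in \[-1, 1\].
#' @param factor Per-axis downsampling factor, `>= 1`.
#' @return A `condition_pair` with task `"SR"`.
#' @export
make_sr_condition <- function(x0, factor) {
  if (!(is.numeric(factor) && length(factor) == 1L && factor >= 1))
    stop("`factor` must be a scalar >= 1")
  h <- max(1L, as.integer(round(nrow(x0) / factor)))
  w <- max(1L, as.integer(round(ncol(x0) / factor)))
  y <- resize_bilinear(resize_area(x0, h, w), nrow(x0), ncol(x0))
  y <- clamp_unit(y)
  condition_pair(x0, y, "SR",
                 meta = list(factor = factor, low_res = c(h, w)))
}

#' Denoising condition: Gaussian plus salt-and-pepper noise
#'
#' `y` is `x0` plus i.i.d. Gaussian noise of standard deviation
#' `gauss_sigma` (on the \[-1, 1\] scale), clipped to \[-1, 1\], after which
#' each pixel is independently replaced with probability `sp_amount` by -1
#' or +1 (equal odds). Reproducible from `seed`.
#'
#' @param x0 Target image in \[-1, 1\].
#' @param gauss_sigma Gaussian noise sd, `>= 0`. Default 0.1.
#' @param sp_amount Expected salt-and-pepper fraction in `[0, 1)`.
#'   Default 0.05.
#' @param seed Optional integer seed.
#' @return A `condition_pair` with task `"DENOISE"`.
#' @export
make_noise_condition <- function(x0, gauss_sigma = 0.1, sp_amount = 0.05,
                                 seed = NULL) {
  if (!(gauss_sigma >= 0)) stop("`gauss_sigma` must be >= 0")
  if (!(sp_amount >= 0 && sp_amount < 1)) stop("`sp_amount` must be in [0, 1)")
  local_seed(seed, {
    y <- x0
    if (gauss_sigma > 0)
      y <- clamp_unit(y + matrix(stats::rnorm(length(x0), sd = gauss_sigma),
                                 nrow(x0)))
    n_sp <- 0L
    if (sp_amount > 0) {
      hit <- stats::runif(length(x0)) < sp_amount
      n_sp <- sum(hit)
      y[hit] <- ifelse(stats::runif(n_sp) < 0.5, -1, 1)
    }
    condition_pair(x0, y, "DENOISE",
                   meta = list(gauss_sigma = gauss_sigma,
                               sp_amount = sp_amount, n_sp = n_sp,
                               seed = seed))
  })
}

#' Random mask specification for inpainting
#'
#' @param kind Mask shape family: `"rectangles"` or `"ellipses"`.
#' @param count Length-2 integer range for the number of shapes.
#' @param size Length-2 range for shape side/axis lengths, as fractions of
#'   the image side.
#' @param seed Integer seed (fixes the mask in test mode).
#' @export
mask_spec <- function(kind = c("rectangles", "ellipses"), count = c(1L, 3L),
                      size = c(0.15, 0.35), seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(length(count) == 2L, count[1] >= 1, count[2] >= count[1],
            length(size) == 2L, size[1] > 0, size[2] <= 1,
            size[2] >= size[1])
  structure(list(kind = kind, count = count, size = size,
                 seed = as.integer(seed)), class = "mask_spec")
}

draw_mask <- function(spec, H, W) {
  m <- matrix(FALSE, H, W)
  k <- if (spec$count[1] == spec$count[2]) spec$count[1] else
    sample(spec$count[1]:spec$count[2], 1L)
  for (i in seq_len(k)) {
    sh <- max(1L, round(stats::runif(1, spec$size[1], spec$size[2]) * H))
    sw <- max(1L, round(stats::runif(1, spec$size[1], spec$size[2]) * W))
    r0 <- sample.int(max(1L, H - sh + 1L), 1L)
    c0 <- sample.int(max(1L, W - sw + 1L), 1L)
    if (spec$kind == "rectangles") {
      m[r0:min(H, r0 + sh - 1L), c0:min(W, c0 + sw - 1L)] <- TRUE
    } else {
      cy <- r0 + (sh - 1) / 2
      cx <- c0 + (sw - 1) / 2
      yy <- matrix(seq_len(H), H, W)
      xx <- matrix(seq_len(W), H, W, byrow = TRUE)
      m <- m | (((yy - cy) / (sh / 2))^2 + ((xx - cx) / (sw / 2))^2 <= 1)
    }
  }
  m
}

#' Inpainting condition: mask out regions of the target
#'
#' Masked pixels of `y` are set to the fill constant (mid-gray, 0); the mask
#' itself is carried on the pair but is not a separate model input. In
#' `"train"` mode a fresh mask is drawn from the caller's RNG stream each
#' call; in `"test"` mode the mask is deterministic from `spec$seed`.
#' Degenerate all-empty or over-half-covered masks are redrawn up to 10
#' times before erroring.
#'
#' @param x0 Target image in \[-1, 1\].
#' @param spec A [mask_spec()].
#' @param mode `"train"` (random mask) or `"test"` (mask fixed by the spec
#'   seed).
#' @param fill Fill value for masked pixels. Default 0.
#' @return A `condition_pair` with task `"INPAINT"` and the mask attached.
#' @export
make_inpaint_condition <- function(x0, spec, mode = c("train", "test"),
                                   fill = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "mask_spec"))
  gen <- function() {
    for (i in 1:10) {
      m <- draw_mask(spec, nrow(x0), ncol(x0))
      fr <- mean(m)
      if (fr > 0 && fr <= 0.5) return(m)
    }
    stop("could not draw a valid mask (fraction in (0, 0.5]) in 10 attempts")
  }
  m <- if (mode == "test") local_seed(spec$seed, gen()) else gen()
  y <- x0
  y[m] <- fill
  condition_pair(x0, y, "INPAINT", mask = m,
                 meta = list(spec = spec, mode = mode, fill = fill,
                             masked_fraction = mean(m)))
}
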
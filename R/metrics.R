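# Image-quality measures: accutance (sharpness), Dice overlap, PSNR.

#' Accutance: mean Sobel gradient magnitude
#'
#' A no-reference sharpness measure: the mean over interior pixels of
#' \eqn{\sqrt{G_x^2 + G_y^2}} with 3x3 Sobel operators applied to the
#' \[-1, 1\] image (border pixels excluded). This operationalization of
#' "accutance" is specific to this package — absolute values are only
#' comparable within it.
#'
#' @param img Numeric matrix, at least 3x3.
#' @return Non-negative scalar.
#' @export
accutance <- function(img) {
  H <- nrow(img)
  W <- ncol(img)
  if (is.null(H) || H < 3 || W < 3) stop("image must be at least 3x3")
  i <- 2:(H - 1)
  j <- 2:(W - 1)
  # Sobel: Gx = [-1 0 1; -2 0 2; -1 0 1] (x = column direction)
  gx <- (img[i - 1, j + 1] + 2 * img[i, j + 1] + img[i + 1, j + 1]) -
        (img[i - 1, j - 1] + 2 * img[i, j - 1] + img[i + 1, j - 1])
  gy <- (img[i + 1, j - 1] + 2 * img[i + 1, j] + img[i + 1, j + 1]) -
        (img[i - 1, j - 1] + 2 * img[i - 1, j] + img[i - 1, j + 1])
  mean(sqrt(gx^2 + gy^2))
}

#' Dice similarity coefficient
#'
#' `2|A intersect B| / (|A| + |B|)` between two binary masks; defined as 1
#' when both masks are empty.
#'
#' @param a,b Logical (or 0/1) matrices of equal shape.
#' @export
dice <- function(a, b) {
  check_same_shape(a, b, "a", "b")
  a <- as.logical(a)
  b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Peak signal-to-noise ratio (dB)
#'
#' `10 * log10(data_range^2 / MSE)`. Identical images (MSE = 0) are
#' reported as a capped 99 dB with attribute `capped = TRUE`.
#'
#' @param ref Reference image.
#' @param test Test image, same shape.
#' @param data_range Dynamic range; default 2 for \[-1, 1\] images.
#' @export
psnr <- function(ref, test, data_range = 2) {
  check_same_shape(ref, test, "ref", "test")
  if (!(data_range > 0)) stop("`data_range` must be positive")
  mse <- mean((ref - test)^2)
  if (mse == 0) return(structure(99, capped = TRUE))
  10 * log10(data_range^2 / mse)
}

#' Evaluate image pairs with a set of metrics
#'
#' @param preds List of predicted images.
#' @param refs List of reference images (same length and shapes).
#' @param metrics Character subset of `c("psnr", "accutance", "dice")`;
#'   for `"dice"` the images are treated as masks by thresholding at 0 (the
#'   midpoint of the \[-1, 1\] scale).
#' @return A `metric_report`: list with `per_image` (data frame),
#'   `aggregate` (mean and sd per metric) and `n`.
#' @export
evaluate_pairs <- function(preds, refs, metrics = c("psnr", "accutance")) {
  stopifnot(length(preds) == length(refs), length(preds) > 0)
  metrics <- match.arg(metrics, c("psnr", "accutance", "dice"),
                       several.ok = TRUE)
  rows <- lapply(seq_along(preds), function(i) {
    v <- c()
    if ("psnr" %in% metrics)
      v <- c(v, psnr = as.numeric(psnr(refs[[i]], preds[[i]])))
    if ("accutance" %in% metrics)
      v <- c(v, accutance = accutance(preds[[i]]))
    if ("dice" %in% metrics)
      v <- c(v, dice = dice(preds[[i]] > 0, refs[[i]] > 0))
    v
  })
  per_image <- as.data.frame(do.call(rbind, rows))
  aggregate <- data.frame(
    metric = names(per_image),
    mean = vapply(per_image, mean, numeric(1)),
    sd = vapply(per_image, stats::sd, numeric(1)),
    row.names = NULL)
  structure(list(per_image = per_image, aggregate = aggregate,
                 n = length(preds)), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> n=%d\n", x$n))
  print(x$aggregate)
  invisible(x)
}
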
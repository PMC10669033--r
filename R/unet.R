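# Reference conditional noise predictor: a small encoder-decoder (U-Net)
# with skip connections, group normalization and sinusoidal time embeddings.
# The condition image y is channel-concatenated with x_t at the input.
# Forward and backward passes are written out explicitly (no autodiff in R);
# gradients are validated against finite differences in the test suite.

groups_for <- function(C, ng) {
  g <- min(ng, C)
  while (C %% g != 0L) g <- g - 1L
  g
}

rb_params <- function(Cin, Cout, D) {
  p <- list(
    gn1_g = rep(1, Cin), gn1_b = rep(0, Cin),
    w1 = matrix(stats::rnorm(9 * Cin * Cout, sd = sqrt(2 / (9 * Cin))),
                9 * Cin, Cout),
    b1 = rep(0, Cout),
    tw = matrix(stats::rnorm(D * Cout, sd = sqrt(1 / D)), D, Cout),
    tb = rep(0, Cout),
    gn2_g = rep(1, Cout), gn2_b = rep(0, Cout),
    w2 = matrix(stats::rnorm(9 * Cout * Cout, sd = sqrt(2 / (9 * Cout))),
                9 * Cout, Cout),
    b2 = rep(0, Cout)
  )
  if (Cin != Cout) {
    p$skip_w <- matrix(stats::rnorm(Cin * Cout, sd = sqrt(1 / Cin)), Cin, Cout)
    p$skip_b <- rep(0, Cout)
  }
  p
}

rb_fwd <- function(pr, A, ste, H, W, N, ng) {
  HW <- H * W
  Cin <- ncol(A)
  g1 <- gn_fwd(A, pr$gn1_g, pr$gn1_b, groups_for(Cin, ng), HW, N)
  s1 <- silu_fwd(g1$out)
  c1 <- conv3_fwd(s1$out, pr$w1, pr$b1, H, W, N)
  pl <- lin_fwd(ste, pr$tw, pr$tb)
  ta <- temb_add_fwd(c1$out, pl$out, HW, N)
  Cout <- ncol(ta$out)
  g2 <- gn_fwd(ta$out, pr$gn2_g, pr$gn2_b, groups_for(Cout, ng), HW, N)
  s2 <- silu_fwd(g2$out)
  c2 <- conv3_fwd(s2$out, pr$w2, pr$b2, H, W, N)
  if (!is.null(pr$skip_w)) {
    sk <- lin_fwd(A, pr$skip_w, pr$skip_b)
    out <- c2$out + sk$out
    skc <- sk$cache
  } else {
    out <- c2$out + A
    skc <- NULL
  }
  list(out = out, cache = list(g1 = g1$cache, s1 = s1$cache, c1 = c1$cache,
                               pl = pl$cache, ta = ta$cache, g2 = g2$cache,
                               s2 = s2$cache, c2 = c2$cache, sk = skc))
}

rb_bwd <- function(pr, cache, dOut) {
  if (!is.null(cache$sk)) {
    skb <- lin_bwd(dOut, cache$sk)
    dA_skip <- skb$dA
  } else {
    dA_skip <- dOut
  }
  c2b <- conv3_bwd(dOut, cache$c2)
  dg2 <- silu_bwd(c2b$dA, cache$s2)
  g2b <- gn_bwd(dg2, cache$g2)
  tab <- temb_add_bwd(g2b$dA, cache$ta)
  plb <- lin_bwd(tab$dP, cache$pl)
  c1b <- conv3_bwd(tab$dA, cache$c1)
  ds1 <- silu_bwd(c1b$dA, cache$s1)
  g1b <- gn_bwd(ds1, cache$g1)
  dA <- g1b$dA + dA_skip
  grads <- list(
    gn1_g = g1b$dgamma, gn1_b = g1b$dbeta,
    w1 = c1b$dW, b1 = c1b$db,
    tw = plb$dW, tb = plb$db,
    gn2_g = g2b$dgamma, gn2_b = g2b$dbeta,
    w2 = c2b$dW, b2 = c2b$db
  )
  if (!is.null(cache$sk)) {
    grads$skip_w <- skb$dW
    grads$skip_b <- skb$db
  }
  list(dA = dA, dste = plb$dA, grads = grads)
}

#' Build the reference conditional U-Net noise predictor
#'
#' An encoder-decoder with one residual block per resolution level, 2x2
#' mean-pool downsampling, nearest-neighbour upsampling with channel
#' concatenation of the encoder skip, group normalization, SiLU activations
#' and a sinusoidal time embedding (dimension `4 * base_channels`) injected
#' into every block. The final convolution is zero-initialized. The
#' architecture itself is this package's construction — only the presence of
#' a U-Net with group normalization is prescribed by the underlying method.
#'
#' @param image_size Side length of (square) inputs; must be divisible by
#'   `2^(length(channel_mults) - 1)`.
#' @param base_channels Channel width at the top resolution. Default 16.
#' @param channel_mults Per-level width multipliers. Default `c(1, 2)`.
#' @param num_groups Group-normalization groups (reduced automatically for
#'   layers whose width it does not divide). Default 8.
#' @param in_channels Input channels; 2 for `concat(x_t, y)`. Default 2.
#' @param seed Integer seed for weight initialization (two builds with equal
#'   seeds have identical parameters).
#' @return An object of classes `ref_unet`, `noise_predictor` with elements
#'   `params`, `arch`, plus methods via [predict_noise()].
#' @export
build_reference_unet <- function(image_size, base_channels = 16L,
                                 channel_mults = c(1L, 2L), num_groups = 8L,
                                 in_channels = 2L, seed = 1L) {
  L <- length(channel_mults)
  div <- 2^(L - 1L)
  if (image_size %% div != 0L)
    stop(sprintf("image_size must be divisible by %d (valid: %s, ...)", div,
                 paste(div * (1:4), collapse = ", ")))
  chs <- as.integer(base_channels * channel_mults)
  D <- 4L * as.integer(base_channels)
  arch <- list(image_size = as.integer(image_size),
               base_channels = as.integer(base_channels),
               channel_mults = channel_mults, num_groups = as.integer(num_groups),
               in_channels = as.integer(in_channels), out_channels = 1L,
               chs = chs, L = L, D = D, seed = as.integer(seed))
  params <- local_seed(seed, {
    p <- list(
      te1_w = matrix(stats::rnorm(D * D, sd = sqrt(1 / D)), D, D),
      te1_b = rep(0, D),
      te2_w = matrix(stats::rnorm(D * D, sd = sqrt(1 / D)), D, D),
      te2_b = rep(0, D),
      conv_in_w = matrix(stats::rnorm(9 * in_channels * chs[1],
                                      sd = sqrt(2 / (9 * in_channels))),
                         9 * in_channels, chs[1]),
      conv_in_b = rep(0, chs[1])
    )
    p$enc <- vector("list", L)
    p$enc[[1]] <- rb_params(chs[1], chs[1], D)
    if (L > 1) for (i in 2:L) p$enc[[i]] <- rb_params(chs[i - 1], chs[i], D)
    p$mid <- rb_params(chs[L], chs[L], D)
    if (L > 1) {
      p$dec <- vector("list", L - 1L)
      for (i in seq_len(L - 1L))
        p$dec[[i]] <- rb_params(chs[i + 1] + chs[i], chs[i], D)
    }
    p$out_gn_g <- rep(1, chs[1])
    p$out_gn_b <- rep(0, chs[1])
    p$out_w <- matrix(0, 9 * chs[1], 1L)
    p$out_b <- rep(0, 1L)
    p
  })
  structure(list(params = params, arch = arch),
            class = c("ref_unet", "noise_predictor"))
}

unet_fwd <- function(params, arch, xt_mat, y_mat, t, N) {
  H <- arch$image_size
  L <- arch$L
  ng <- arch$num_groups
  te0 <- time_embedding(t, arch$D)
  l1 <- lin_fwd(te0, params$te1_w, params$te1_b)
  s1 <- silu_fwd(l1$out)
  l2 <- lin_fwd(s1$out, params$te2_w, params$te2_b)
  ss <- silu_fwd(l2$out)
  ste <- ss$out
  A0 <- cbind(xt_mat, y_mat)
  ci <- conv3_fwd(A0, params$conv_in_w, params$conv_in_b, H, H, N)
  h <- ci$out
  enc_c <- vector("list", L)
  pool_c <- vector("list", L)
  skips <- vector("list", L)
  Hw <- H
  for (i in seq_len(L)) {
    if (i > 1L) {
      pf <- pool_fwd(h, pool_indices(Hw, Hw, N))
      pool_c[[i]] <- pf$cache
      h <- pf$out
      Hw <- Hw %/% 2L
    }
    rf <- rb_fwd(params$enc[[i]], h, ste, Hw, Hw, N, ng)
    enc_c[[i]] <- rf$cache
    h <- rf$out
    skips[[i]] <- h
  }
  mf <- rb_fwd(params$mid, h, ste, Hw, Hw, N, ng)
  h <- mf$out
  dec_c <- vector("list", max(L - 1L, 0L))
  up_c <- vector("list", max(L - 1L, 0L))
  if (L > 1L) for (i in seq(L - 1L, 1L)) {
    uf <- up_fwd(h, upsample_indices(Hw, Hw, N))
    up_c[[i]] <- uf$cache
    Hw <- Hw * 2L
    h <- cbind(uf$out, skips[[i]])
    rf <- rb_fwd(params$dec[[i]], h, ste, Hw, Hw, N, ng)
    dec_c[[i]] <- rf$cache
    h <- rf$out
  }
  og <- gn_fwd(h, params$out_gn_g, params$out_gn_b,
               groups_for(ncol(h), ng), Hw * Hw, N)
  os <- silu_fwd(og$out)
  oc <- conv3_fwd(os$out, params$out_w, params$out_b, Hw, Hw, N)
  list(out = oc$out,
       cache = list(l1 = l1$cache, s1 = s1$cache, l2 = l2$cache, ss = ss$cache,
                    ci = ci$cache, enc = enc_c, pool = pool_c, mid = mf$cache,
                    up = up_c, dec = dec_c, og = og$cache, os = os$cache,
                    oc = oc$cache, N = N))
}

unet_bwd <- function(params, arch, fw, dOut) {
  L <- arch$L
  cache <- fw$cache
  g <- list()
  ocb <- conv3_bwd(dOut, cache$oc)
  g$out_w <- ocb$dW
  g$out_b <- ocb$db
  dos <- silu_bwd(ocb$dA, cache$os)
  ogb <- gn_bwd(dos, cache$og)
  g$out_gn_g <- ogb$dgamma
  g$out_gn_b <- ogb$dbeta
  dh <- ogb$dA
  dste <- 0
  dskips <- vector("list", L)
  g$dec <- vector("list", max(L - 1L, 0L))
  if (L > 1L) for (i in seq_len(L - 1L)) {
    rb <- rb_bwd(params$dec[[i]], cache$dec[[i]], dh)
    g$dec[[i]] <- rb$grads
    dste <- dste + rb$dste
    Cup <- arch$chs[i + 1]
    d_up <- rb$dA[, seq_len(Cup), drop = FALSE]
    dskips[[i]] <- rb$dA[, -seq_len(Cup), drop = FALSE]
    dh <- up_bwd(d_up, cache$up[[i]])
  }
  rb <- rb_bwd(params$mid, cache$mid, dh)
  g$mid <- rb$grads
  dste <- dste + rb$dste
  dh <- rb$dA
  g$enc <- vector("list", L)
  for (i in seq(L, 1L)) {
    if (!is.null(dskips[[i]])) dh <- dh + dskips[[i]]
    rb <- rb_bwd(params$enc[[i]], cache$enc[[i]], dh)
    g$enc[[i]] <- rb$grads
    dste <- dste + rb$dste
    dh <- rb$dA
    if (i > 1L) dh <- pool_bwd(dh, cache$pool[[i]])
  }
  cib <- conv3_bwd(dh, cache$ci)
  g$conv_in_w <- cib$dW
  g$conv_in_b <- cib$db
  dss <- silu_bwd(dste, cache$ss)
  l2b <- lin_bwd(dss, cache$l2)
  g$te2_w <- l2b$dW
  g$te2_b <- l2b$db
  ds1 <- silu_bwd(l2b$dA, cache$s1)
  l1b <- lin_bwd(ds1, cache$l1)
  g$te1_w <- l1b$dW
  g$te1_b <- l1b$db
  g
}

as_batch_mat <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) matrix(as.vector(x), ncol = 1L)
  else matrix(as.vector(x), ncol = 1L)
}

batch_size_of <- function(x) if (length(dim(x)) == 3L) dim(x)[3L] else 1L

#' Predict noise with a noise predictor
#'
#' Generic evaluation interface: `eps_hat = model(x_t, y, t)`. Inputs are
#' never mutated; output has the shape of `xt`.
#'
#' @param model A `noise_predictor`.
#' @param xt Noised image (matrix or H x W x N array).
#' @param y Condition image, same shape.
#' @param t Timestep: scalar, or a length-N vector for batched input.
#' @export
predict_noise <- function(model, xt, y, t) UseMethod("predict_noise")

#' @export
predict_noise.ref_unet <- function(model, xt, y, t) {
  check_same_shape(xt, y, "xt", "y")
  N <- batch_size_of(xt)
  if (length(t) == 1L) t <- rep(t, N)
  if (length(t) != N) stop("length(t) must be 1 or the batch size")
  d <- dim(xt)
  if (d[1L] != model$arch$image_size || d[2L] != model$arch$image_size)
    stop(sprintf("model expects %dx%d images", model$arch$image_size,
                 model$arch$image_size))
  fw <- unet_fwd(model$params, model$arch, as_batch_mat(xt), as_batch_mat(y),
                 t, N)
  array(fw$out, dim = d)
}

#' Wrap a plain function as a noise predictor
#'
#' Useful for oracle models in tests (e.g. a predictor that returns a stored
#' true noise field regardless of its inputs).
#'
#' @param fn Function `(xt, y, t) -> eps_hat`.
#' @param name Fingerprint label.
#' @export
as_noise_predictor <- function(fn, name = "custom") {
  structure(list(fn = fn, name = name),
            class = c("fn_predictor", "noise_predictor"))
}

#' @export
predict_noise.fn_predictor <- function(model, xt, y, t) model$fn(xt, y, t)

#' Number of trainable parameters
#' @param model A `noise_predictor`.
#' @export
n_params <- function(model) UseMethod("n_params")

#' @export
n_params.ref_unet <- function(model)
  sum(vapply(flatten_params(model$params), length, integer(1)))

#' @export
n_params.fn_predictor <- function(model) 0L

#' Configuration/weight fingerprint of a model
#' @param model A `noise_predictor`.
#' @export
model_fingerprint <- function(model) UseMethod("model_fingerprint")

#' @export
model_fingerprint.ref_unet <- function(model) {
  fl <- flatten_params(model$params)
  h <- sum(vapply(fl, function(m) sum(as.vector(m) * seq_along(m)) %% 1e9,
                  numeric(1)))
  sprintf("ref_unet[%dpx,b%d,%s]#%.6f", model$arch$image_size,
          model$arch$base_channels,
          paste(model$arch$channel_mults, collapse = "-"), h %% 1e6)
}

#' @export
model_fingerprint.fn_predictor <- function(model) model$name

# ---- parameter-tree helpers ------------------------------------------------

flatten_params <- function(p, prefix = "") {
  out <- list()
  nms <- names(p)
  if (is.null(nms)) nms <- as.character(seq_along(p))
  for (k in seq_along(p)) {
    nm <- if (nzchar(nms[k])) nms[k] else as.character(k)
    key <- if (prefix == "") nm else paste(prefix, nm, sep = ".")
    v <- p[[k]]
    if (is.list(v)) out <- c(out, flatten_params(v, key))
    else out[[key]] <- v
  }
  out
}

# elementwise combine two parameter trees with the same leaves
# (matched by name where names exist, by position otherwise)
map_params2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    nms <- names(a)
    for (k in seq_along(a)) {
      bk <- if (!is.null(nms) && nzchar(nms[k])) b[[nms[k]]] else b[[k]]
      out[[k]] <- map_params2(f, a[[k]], bk)
    }
    out
  } else f(a, b)
}

get_param_leaf <- function(p, key) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  for (pt in parts) {
    idx <- suppressWarnings(as.integer(pt))
    p <- if (!is.na(idx) && is.null(names(p))) p[[idx]] else p[[pt]]
  }
  p
}

set_param_leaf <- function(p, key, value) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1L) {
    p[[parts]] <- value
    return(p)
  }
  head <- parts[1L]
  idx <- suppressWarnings(as.integer(head))
  kk <- if (!is.na(idx) && is.null(names(p))) idx else head
  p[[kk]] <- set_param_leaf(p[[kk]], paste(parts[-1L], collapse = "."), value)
  p
}
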
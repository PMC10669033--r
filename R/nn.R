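# Minimal neural-network primitives with hand-written backward passes.
# Activations are (H*W*N) x C matrices whose rows run h-fastest, then w,
# then n — the flattening of an (H, W, N, C) array. The 3x3 convolution is
# the only compiled kernel (src/conv3.cpp); everything else is vector math.

silu_fwd <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(out = x * s, cache = list(x = x, s = s))
}

silu_bwd <- function(dY, cache) {
  s <- cache$s
  dY * (s * (1 + cache$x * (1 - s)))
}

conv3_fwd <- function(A, W, b, H, Wd, N) {
  r <- conv3_forward(as.vector(A), H, Wd, N, ncol(A), W, b)
  list(out = r$out, cache = list(col = r$col, W = W, H = H, Wd = Wd, N = N,
                                 Cin = ncol(A)))
}

conv3_bwd <- function(dY, cache) {
  r <- conv3_backward(cache$col, cache$W, dY, cache$H, cache$Wd, cache$N,
                      cache$Cin)
  list(dA = matrix(r$dX, nrow = nrow(dY)), dW = r$dW, db = as.vector(r$db))
}

# 1x1 convolution = channel-mixing matmul; used for residual skips
lin_fwd <- function(A, W, b) {
  list(out = sweep(A %*% W, 2, b, "+"), cache = list(A = A, W = W))
}

lin_bwd <- function(dY, cache) {
  list(dA = dY %*% t(cache$W), dW = t(cache$A) %*% dY, db = colSums(dY))
}

GN_EPS <- 1e-5

# per-(sample, group) means of an activation matrix, as an N x groups matrix
gn_region_means <- function(A, rowg, colg, HW, gs) {
  cs <- rowsum(A, group = rowg, reorder = FALSE)        # N x C per-sample sums
  t(rowsum(t(cs), group = colg, reorder = FALSE)) / (HW * gs)  # N x groups
}

# expand an N x groups matrix to the full (HW*N) x C activation shape
gn_expand <- function(M, rowg, colg) {
  M[rowg, colg, drop = FALSE]
}

gn_fwd <- function(A, gamma, beta, groups, HW, N) {
  C <- ncol(A)
  gs <- C %/% groups
  rowg <- rep(seq_len(N), each = HW)
  colg <- rep(seq_len(groups), each = gs)
  mu <- gn_region_means(A, rowg, colg, HW, gs)
  mu_e <- gn_expand(mu, rowg, colg)
  cen <- A - mu_e
  v <- gn_region_means(cen * cen, rowg, colg, HW, gs)
  istd <- 1 / sqrt(v + GN_EPS)
  xhat <- cen * gn_expand(istd, rowg, colg)
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out, cache = list(xhat = xhat, istd = istd, gamma = gamma,
                               groups = groups, HW = HW, N = N, gs = gs,
                               rowg = rowg, colg = colg))
}

gn_bwd <- function(dY, cache) {
  xhat <- cache$xhat
  rowg <- cache$rowg
  colg <- cache$colg
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, cache$gamma, "*")
  m1 <- gn_region_means(dxhat, rowg, colg, cache$HW, cache$gs)
  m2 <- gn_region_means(dxhat * xhat, rowg, colg, cache$HW, cache$gs)
  dA <- gn_expand(cache$istd, rowg, colg) *
    (dxhat - gn_expand(m1, rowg, colg) - xhat * gn_expand(m2, rowg, colg))
  list(dA = dA, dgamma = dgamma, dbeta = dbeta)
}

# Row-index maps for 2x2 mean pooling and nearest-neighbour x2 upsampling,
# for rows ordered (h, w, n). Cached per geometry by the caller.
pool_indices <- function(H, W, N) {
  H2 <- H %/% 2L
  W2 <- W %/% 2L
  h2 <- rep(seq_len(H2), times = W2 * N)
  w2 <- rep(rep(seq_len(W2), each = H2), times = N)
  n <- rep(seq_len(N), each = H2 * W2)
  base <- function(dh, dw) {
    (2L * h2 - 2L + dh) + (2L * w2 - 2L + dw) * H + (n - 1L) * H * W + 1L
  }
  list(i00 = base(0L, 0L), i10 = base(1L, 0L), i01 = base(0L, 1L),
       i11 = base(1L, 1L), H2 = H2, W2 = W2)
}

pool_fwd <- function(A, idx) {
  out <- (A[idx$i00, , drop = FALSE] + A[idx$i10, , drop = FALSE] +
            A[idx$i01, , drop = FALSE] + A[idx$i11, , drop = FALSE]) / 4
  list(out = out, cache = list(idx = idx, n_in = nrow(A)))
}

pool_bwd <- function(dY, cache) {
  dA <- matrix(0, cache$n_in, ncol(dY))
  q <- dY / 4
  dA[cache$idx$i00, ] <- q
  dA[cache$idx$i10, ] <- q
  dA[cache$idx$i01, ] <- q
  dA[cache$idx$i11, ] <- q
  dA
}

# upsample x2 (nearest): source-row index for each of the (2H)*(2W)*N rows
upsample_indices <- function(H, W, N) {
  h2 <- rep(seq_len(2L * H), times = 2L * W * N)
  w2 <- rep(rep(seq_len(2L * W), each = 2L * H), times = N)
  n <- rep(seq_len(N), each = 4L * H * W)
  src <- ((h2 + 1L) %/% 2L - 1L) + ((w2 + 1L) %/% 2L - 1L) * H +
    (n - 1L) * H * W + 1L
  src
}

up_fwd <- function(A, src) {
  list(out = A[src, , drop = FALSE], cache = list(src = src, n_in = nrow(A)))
}

up_bwd <- function(dY, cache) {
  dA <- rowsum(dY, group = cache$src)
  # rowsum orders by sorted unique group; every source row appears
  dA[order(as.integer(rownames(dA))), , drop = FALSE]
}

# sinusoidal timestep embedding, dimension D (even)
time_embedding <- function(t, D) {
  half <- D %/% 2L
  freqs <- if (half == 1L) 1 else
    exp(-log(10000) * (seq_len(half) - 1) / (half - 1))
  ang <- outer(as.numeric(t), freqs)
  cbind(sin(ang), cos(ang))
}

# broadcast a per-sample (N x C) projection over the HW rows of each sample
temb_add_fwd <- function(A, P, HW, N) {
  list(out = A + P[rep(seq_len(N), each = HW), , drop = FALSE],
       cache = list(HW = HW, N = N))
}

temb_add_bwd <- function(dY, cache) {
  dP <- rowsum(dY, group = rep(seq_len(cache$N), each = cache$HW))
  list(dA = dY, dP = dP)
}
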
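# Internal dense-array primitives.
#
# Tensors are 4-D numeric arrays laid out (channel, height, width, batch).
# Channel-major layout lets every kernel tap reduce to one BLAS matrix
# product over (channel) x (height*width*batch), which is what keeps the
# pure-R unrolled training loop fast enough for desk-scale experiments.

pad_hw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1L], d[2L] + 2L * p, d[3L] + 2L * p, d[4L]))
  out[, (p + 1L):(p + d[2L]), (p + 1L):(p + d[3L]), ] <- x
  out
}

# 2-D cross-correlation, stride 1, zero padding. W: (c_out, c_in, k, k).
# Hot path: compiled im2col + GEMM. The pure-R implementation below is kept
# as the slow reference used in correctness tests.
conv2d_fwd <- function(x, W, b, pad = 1L) {
  stopifnot(dim(W)[2L] == dim(x)[1L])
  .cpp_conv2d_fwd(x, dim(x), W, dim(W), b, as.integer(pad))
}

conv2d_bwd <- function(dy, x, W, pad = 1L) {
  .cpp_conv2d_bwd(dy, x, dim(x), W, dim(W), as.integer(pad))
}

conv2d_fwd_ref <- function(x, W, b, pad = 1L) {
  d <- dim(x); H <- d[2L]; Wd <- d[3L]; N <- d[4L]
  k <- dim(W)[3L]; cout <- dim(W)[1L]; cin <- dim(W)[2L]
  stopifnot(cin == d[1L])
  xp <- pad_hw(x, pad)
  M <- H * Wd * N
  acc <- matrix(0, cout, M)
  for (ki in seq_len(k)) {
    hs <- ki:(ki + H - 1L)
    for (kj in seq_len(k)) {
      xs <- xp[, hs, kj:(kj + Wd - 1L), , drop = FALSE]
      dim(xs) <- c(cin, M)
      acc <- acc + matrix(W[, , ki, kj], cout, cin) %*% xs
    }
  }
  acc <- acc + b  # recycles down columns: one bias per output channel
  dim(acc) <- c(cout, H, Wd, N)
  acc
}

conv2d_bwd_ref <- function(dy, x, W, pad = 1L) {
  d <- dim(x); H <- d[2L]; Wd <- d[3L]; N <- d[4L]
  k <- dim(W)[3L]; cout <- dim(W)[1L]; cin <- dim(W)[2L]
  xp <- pad_hw(x, pad)
  dW <- array(0, dim(W))
  M <- H * Wd * N
  dym <- dy
  dim(dym) <- c(cout, M)
  db <- rowSums(dym)
  for (ki in seq_len(k)) {
    hs <- ki:(ki + H - 1L)
    for (kj in seq_len(k)) {
      xs <- xp[, hs, kj:(kj + Wd - 1L), , drop = FALSE]
      dim(xs) <- c(cin, M)
      dW[, , ki, kj] <- tcrossprod(dym, xs)
    }
  }
  # input gradient = correlation of dy with the spatially flipped,
  # channel-transposed kernel (valid for stride 1)
  Wf <- aperm(W, c(2L, 1L, 3L, 4L))[, , k:1, k:1, drop = FALSE]
  dx <- conv2d_fwd_ref(dy, Wf, numeric(cin), pad = k - 1L - pad)
  list(dx = dx, dW = dW, db = db)
}

# Transposed convolution (deconvolution). W: (c_in, c_out, k, k).
# Output size: (H - 1) * stride - 2 * pad + k.
deconv2d_fwd <- function(x, W, b, stride = 2L, pad = 1L) {
  d <- dim(x); H <- d[2L]; Wd <- d[3L]; N <- d[4L]
  k <- dim(W)[3L]; cin <- dim(W)[1L]; cout <- dim(W)[2L]
  stopifnot(cin == d[1L])
  Ho <- (H - 1L) * stride - 2L * pad + k
  Wo <- (Wd - 1L) * stride - 2L * pad + k
  out <- array(0, c(cout, Ho, Wo, N))
  for (ki in seq_len(k)) {
    pi <- stride * (seq_len(H) - 1L) + ki - pad  # output rows hit by tap ki
    iok <- which(pi >= 1L & pi <= Ho)
    if (!length(iok)) next
    for (kj in seq_len(k)) {
      pj <- stride * (seq_len(Wd) - 1L) + kj - pad
      jok <- which(pj >= 1L & pj <= Wo)
      if (!length(jok)) next
      xs <- x[, iok, jok, , drop = FALSE]
      dim(xs) <- c(cin, length(iok) * length(jok) * N)
      ys <- crossprod(matrix(W[, , ki, kj], cin, cout), xs)
      dim(ys) <- c(cout, length(iok), length(jok), N)
      out[, pi[iok], pj[jok], ] <-
        out[, pi[iok], pj[jok], , drop = FALSE] + ys
    }
  }
  out + array(rep(b, times = Ho * Wo * N), c(cout, Ho, Wo, N))
}

deconv2d_bwd <- function(dy, x, W, stride = 2L, pad = 1L) {
  d <- dim(x); H <- d[2L]; Wd <- d[3L]; N <- d[4L]
  k <- dim(W)[3L]; cin <- dim(W)[1L]; cout <- dim(W)[2L]
  do <- dim(dy); Ho <- do[2L]; Wo <- do[3L]
  dx <- array(0, dim(x))
  dW <- array(0, dim(W))
  dym <- dy
  dim(dym) <- c(cout, Ho * Wo * N)
  db <- rowSums(dym)
  for (ki in seq_len(k)) {
    pi <- stride * (seq_len(H) - 1L) + ki - pad
    iok <- which(pi >= 1L & pi <= Ho)
    if (!length(iok)) next
    for (kj in seq_len(k)) {
      pj <- stride * (seq_len(Wd) - 1L) + kj - pad
      jok <- which(pj >= 1L & pj <= Wo)
      if (!length(jok)) next
      m <- length(iok) * length(jok) * N
      dys <- dy[, pi[iok], pj[jok], , drop = FALSE]
      dim(dys) <- c(cout, m)
      xs <- x[, iok, jok, , drop = FALSE]
      dim(xs) <- c(cin, m)
      dW[, , ki, kj] <- xs %*% t(dys)
      dxs <- matrix(W[, , ki, kj], cin, cout) %*% dys
      dim(dxs) <- c(cin, length(iok), length(jok), N)
      dx[, iok, jok, ] <- dx[, iok, jok, , drop = FALSE] + dxs
    }
  }
  list(dx = dx, dW = dW, db = db)
}

# 2x2 average pooling, stride 2 (spatial halving).
avgpool2_fwd <- function(x) {
  d <- dim(x)
  i1 <- seq(1L, d[2L], 2L); i2 <- seq(2L, d[2L], 2L)
  j1 <- seq(1L, d[3L], 2L); j2 <- seq(2L, d[3L], 2L)
  (x[, i1, j1, , drop = FALSE] + x[, i2, j1, , drop = FALSE] +
     x[, i1, j2, , drop = FALSE] + x[, i2, j2, , drop = FALSE]) / 4
}

avgpool2_bwd <- function(dy, in_dim) {
  dx <- array(0, in_dim)
  i1 <- seq(1L, in_dim[2L], 2L); i2 <- seq(2L, in_dim[2L], 2L)
  j1 <- seq(1L, in_dim[3L], 2L); j2 <- seq(2L, in_dim[3L], 2L)
  q <- dy / 4
  dx[, i1, j1, ] <- q; dx[, i2, j1, ] <- q
  dx[, i1, j2, ] <- q; dx[, i2, j2, ] <- q
  dx
}

linear_fwd <- function(x, W, b) W %*% x + b

linear_bwd <- function(dy, x, W) {
  list(dx = crossprod(W, dy), dW = dy %*% t(x), db = rowSums(dy))
}

# Layer normalization over all elements of each column (one column = one
# sample's flattened map); no learned affine terms.
layernorm_fwd <- function(x, eps = 1e-5) {
  P <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  v <- colSums(xc^2) / P
  istd <- 1 / sqrt(v + eps)
  z <- sweep(xc, 2L, istd, `*`)
  list(z = z, istd = istd)
}

layernorm_bwd <- function(dz, cache) {
  z <- cache$z
  m1 <- colMeans(dz)
  m2 <- colMeans(dz * z)
  sweep(dz - rep(m1, each = nrow(dz)) - sweep(z, 2L, m2, `*`),
        2L, cache$istd, `*`)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu_fwd <- function(x) {
  x[x < 0] <- 0
  x
}

# Sum over the channel dimension of a (C, H, W, N) array -> (1, H, W, N).
channel_sum <- function(x) {
  d <- dim(x)
  out <- colSums(matrix(x, d[1L], prod(d[-1L])))
  dim(out) <- c(1L, d[2L], d[3L], d[4L])
  out
}

# Broadcast a (1, H, W, N) gate over C channels.
broadcast_gate <- function(m, C) {
  if (C == 1L) return(m)
  d <- dim(m)
  out <- array(0, c(C, d[2L], d[3L], d[4L]))
  for (c in seq_len(C)) out[c, , , ] <- m
  out
}
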
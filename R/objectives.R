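#' Mixing weights of the joint training objective
#'
#' The joint objective is `alpha * L_C + (1 - alpha) * L_M`, where `L_C` is
#' the softmax cross-entropy classification loss and `L_M` the weakly
#' supervised attention objective. Within `L_M`, `gamma` weights the L1
#' sparsity term, `beta` the (negated) variance/diversity term, and the
#' remainder `1 - gamma - beta` the high-pass smoothness term, so
#' `gamma + beta` may not exceed 1.
#'
#' Defaults are the grid-searched settings used for textured static scenes:
#' `alpha = 0.10`, `beta = 0.40`, `gamma = 0.51`.
#'
#' @param alpha Classification-loss weight, in `[0, 1]`.
#' @param beta Variance-term weight, `>= 0`.
#' @param gamma Sparsity-term weight, `>= 0`.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 0.10, beta = 0.40, gamma = 0.51) {
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]", call. = FALSE)
  if (beta < 0 || gamma < 0) stop("`beta` and `gamma` must be >= 0", call. = FALSE)
  if (beta + gamma > 1 + 1e-12) {
    stop("`beta + gamma` must not exceed 1 (smoothness weight 1 - beta - gamma)",
         call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "loss_weights")
}

#' High-pass filter kernels for the smoothness term
#'
#' `laplacian_kernel()` returns the 4-neighbor Laplacian stencil
#' `[[0,1,0],[1,-4,1],[0,1,0]]`, the default high-pass kernel of the
#' attention smoothness penalty. `highpass_kernel()` validates an arbitrary
#' 3x3 stencil: its coefficients must sum to zero so that constant maps pass
#' no signal. A kernel carries its boundary-handling rule: `"mirror"`
#' (reflect about the edge pixel; the default) or `"replicate"` (repeat the
#' edge pixel). Both pass no constant signal; mirror padding additionally
#' prices a transition hugging the map border like the same transition in
#' the interior, which keeps the smoothness term from being satisfied by
#' parking gates along the edge.
#'
#' @param k A 3x3 numeric matrix of signed coefficients.
#' @param boundary Boundary-handling rule, `"mirror"` or `"replicate"`.
#' @return The kernel matrix with class `highpass_kernel` and attribute
#'   `boundary`.
#' @export
laplacian_kernel <- function(boundary = c("mirror", "replicate")) {
  highpass_kernel(matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3L, 3L),
                  boundary = boundary)
}

#' @rdname laplacian_kernel
#' @export
highpass_kernel <- function(k, boundary = c("mirror", "replicate")) {
  boundary <- match.arg(boundary)
  stopifnot(is.matrix(k), all(dim(k) == c(3L, 3L)))
  if (abs(sum(k)) > 1e-9) {
    stop("high-pass kernel coefficients must sum to 0", call. = FALSE)
  }
  structure(k, class = c("highpass_kernel", "matrix", "array"),
            boundary = boundary)
}

#' Softmax cross-entropy classification loss
#'
#' `-log softmax(Y)[label]`, averaged over samples when `Y` is a matrix with
#' one column per sample.
#'
#' @param Y Class-score vector, or matrix (`n_class` x `n_samples`).
#' @param label Integer class index (1-based), one per sample.
#' @return Scalar loss.
#' @export
classification_loss <- function(Y, label) {
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1L)
  if (nrow(Y) < 2L) stop("`Y` needs at least 2 class scores", call. = FALSE)
  label <- as.integer(label)
  if (any(label < 1L | label > nrow(Y))) {
    stop("`label` out of range", call. = FALSE)
  }
  if (length(label) != ncol(Y)) stop("one label per sample", call. = FALSE)
  p <- softmax_cols(Y)
  -mean(log(pmax(p[cbind(label, seq_len(ncol(Y)))], 1e-300)))
}

#' Weakly supervised attention-map objective
#'
#' The per-map penalty averages three terms over the `N` generated maps and
#' `P` gates per map:
#' `(1/(N P)) * sum_n [ gamma * ||M_n||_1  -  beta * ||M_n - mean(M_n)||_2^2
#'  + (1 - gamma - beta) * ||M_n * K||_1 ]`,
#' i.e. an L1 sparsity pull toward empty maps, a variance reward that pushes
#' gates toward 0 or 1, and an L1 high-pass penalty that makes the attended
#' region spatially coherent. The high-pass correlation uses mirror
#' boundary padding, so constant maps incur exactly zero smoothness penalty
#' and the all-ones map scores exactly `gamma`, while border-hugging
#' transitions are priced like interior ones.
#'
#' @param maps A single gate matrix or a list of them (all the same size).
#' @param weights A [loss_weights()] (only `beta` and `gamma` are used).
#' @param kernel A [highpass_kernel()]; default [laplacian_kernel()].
#' @return Scalar loss value.
#' @export
attention_loss <- function(maps, weights = loss_weights(),
                           kernel = laplacian_kernel()) {
  if (!is.list(maps)) maps <- list(maps)
  if (length(maps) < 1L) stop("need at least one map", call. = FALSE)
  d1 <- dim(maps[[1L]])
  batched <- lapply(maps, function(m) {
    m <- unclass(m)
    if (!is.matrix(m) || !all(dim(m) == d1)) {
      stop("all maps must be matrices of identical size", call. = FALSE)
    }
    array(m, c(1L, d1[1L], d1[2L], 1L))
  })
  attention_loss_batch(batched, weights, kernel)$value
}

# Batched core: maps is a list over map indices of (1, H, W, B) arrays.
# Loss is the mean over the B samples of the per-sample (1/(N P)) sum.
attention_loss_batch <- function(maps, weights, kernel, gradient = FALSE) {
  Nm <- length(maps)
  d <- dim(maps[[1L]])
  H <- d[2L]; W <- d[3L]; B <- d[4L]
  P <- H * W
  kern <- unclass(kernel)
  boundary <- attr(kernel, "boundary") %||% "mirror"
  w3 <- 1 - weights$gamma - weights$beta
  l1_tot <- 0; var_tot <- 0; sm_tot <- 0
  grads <- if (gradient) vector("list", Nm) else NULL
  for (n in seq_len(Nm)) {
    m3 <- maps[[n]]
    dim(m3) <- c(H, W, B)
    mu <- colMeans(matrix(m3, P, B))
    mc <- sweep_3d(m3, mu)
    r <- hp3_fwd(m3, kern, boundary)
    l1_tot <- l1_tot + sum(abs(m3))
    var_tot <- var_tot + sum(mc^2)
    sm_tot <- sm_tot + sum(abs(r))
    if (gradient) {
      dsm <- hp3_adjoint(sign(r) * w3, kern, boundary)
      dm <- (weights$gamma * sign(m3) - 2 * weights$beta * mc + dsm) /
        (B * Nm * P)
      dim(dm) <- c(1L, H, W, B)
      grads[[n]] <- dm
    }
  }
  scale <- 1 / (B * Nm * P)
  terms <- c(l1 = weights$gamma * l1_tot * scale,
             variance = -weights$beta * var_tot * scale,
             smooth = w3 * sm_tot * scale)
  list(value = sum(terms), terms = terms, grads = grads)
}

sweep_3d <- function(m3, mu) {
  d <- dim(m3)
  out <- matrix(m3, d[1L] * d[2L], d[3L])
  out <- sweep(out, 2L, mu)
  dim(out) <- d
  out
}

# 3x3 correlation with mirror (reflect-101) boundary padding on an
# (H, W, B) array. Mirror padding passes no constant signal (a constant
# map has exactly zero high-pass response) and -- unlike replicate
# padding -- prices a transition hugging the border like the same
# transition in the interior, so the smoothness term cannot be satisfied
# by parking gates along the image edge.
hp_pad_idx <- function(n, boundary) {
  if (boundary == "mirror") c(2L, seq_len(n), n - 1L)
  else c(1L, seq_len(n), n)
}

hp3_fwd <- function(x, kern, boundary = "mirror") {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]
  xp <- x[hp_pad_idx(H, boundary), hp_pad_idx(W, boundary), , drop = FALSE]
  out <- array(0, d)
  for (ki in 1:3) for (kj in 1:3) {
    if (kern[ki, kj] == 0) next
    out <- out + kern[ki, kj] *
      xp[ki:(ki + H - 1L), kj:(kj + W - 1L), , drop = FALSE]
  }
  out
}

# Exact adjoint of hp3_fwd (transpose of padding + correlation).
hp3_adjoint <- function(s, kern, boundary = "mirror") {
  d <- dim(s)
  H <- d[1L]; W <- d[2L]; B <- d[3L]
  dxp <- array(0, c(H + 2L, W + 2L, B))
  for (ki in 1:3) for (kj in 1:3) {
    if (kern[ki, kj] == 0) next
    hs <- ki:(ki + H - 1L); ws <- kj:(kj + W - 1L)
    dxp[hs, ws, ] <- dxp[hs, ws, , drop = FALSE] + kern[ki, kj] * s
  }
  ri <- hp_pad_idx(H, boundary); ci <- hp_pad_idx(W, boundary)
  dm <- dxp[2:(H + 1L), 2:(W + 1L), , drop = FALSE]
  dm[ri[1L], , ] <- dm[ri[1L], , ] + dxp[1L, 2:(W + 1L), ]
  dm[ri[H + 2L], , ] <- dm[ri[H + 2L], , ] + dxp[H + 2L, 2:(W + 1L), ]
  dm[, ci[1L], ] <- dm[, ci[1L], ] + dxp[2:(H + 1L), 1L, ]
  dm[, ci[W + 2L], ] <- dm[, ci[W + 2L], ] + dxp[2:(H + 1L), W + 2L, ]
  dm[ri[1L], ci[1L], ] <- dm[ri[1L], ci[1L], ] + dxp[1L, 1L, ]
  dm[ri[1L], ci[W + 2L], ] <- dm[ri[1L], ci[W + 2L], ] + dxp[1L, W + 2L, ]
  dm[ri[H + 2L], ci[1L], ] <- dm[ri[H + 2L], ci[1L], ] + dxp[H + 2L, 1L, ]
  dm[ri[H + 2L], ci[W + 2L], ] <- dm[ri[H + 2L], ci[W + 2L], ] +
    dxp[H + 2L, W + 2L, ]
  dm
}

#' Apply a high-pass kernel to one map
#'
#' 2-D cross-correlation with mirror boundary padding; output size equals
#' the map size. Used by the smoothness term of [attention_loss()].
#'
#' @param m A numeric matrix.
#' @param kernel A [highpass_kernel()].
#' @return The filtered matrix.
#' @export
highpass_filter <- function(m, kernel = laplacian_kernel()) {
  stopifnot(is.matrix(m))
  r <- hp3_fwd(array(m, c(dim(m), 1L)), unclass(kernel),
               attr(kernel, "boundary") %||% "mirror")
  matrix(r, nrow(m), ncol(m))
}

#' Combine classification and attention losses
#'
#' `alpha * L_C + (1 - alpha) * L_M`.
#'
#' @param L_C Classification loss.
#' @param L_M Attention loss.
#' @param alpha Mixing weight in `[0, 1]`.
#' @return Scalar total loss.
#' @export
total_loss <- function(L_C, L_M, alpha = 0.10) {
  stopifnot(alpha >= 0, alpha <= 1)
  alpha * L_C + (1 - alpha) * L_M
}
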
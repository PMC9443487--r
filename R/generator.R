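# The analog attention-map generator: a small 3-layer deconvolutional
# network that maps time-integrated spiking features from the extractor's
# tap point to a single-channel pre-normalization map at input resolution.
# Stride-2 kernel-4 transposed-convolution layers (each an exact spatial
# doubling at padding 1) supply the required upsampling factor; any
# remaining layers are stride-1 3x3 convolutions. ReLU sits between layers.

#' Construct an attention-map generator
#'
#' Builds the layer plan and (Kaiming-uniform) initial weights for the
#' generator. Channel widths taper `c -> c/2 -> c/4 -> 1` where `c` is the
#' tap width; the number of stride-2 transposed-convolution layers equals
#' `log2(out_size / tap_size)`.
#'
#' @param tap_channels Channel count at the extractor tap point.
#' @param tap_size Spatial size (square) of the tap features.
#' @param out_size Spatial size of the input (and of the generated map).
#' @param n_layers Number of layers (default 3).
#'
#' The output layer is zero-initialized, so an untrained generator emits a
#' constant pre-map and — after normalization and squashing — an exactly
#' uniform gate field of 0.5: the initial attention expresses no spatial
#' preference of its own, and any preference that develops is driven by
#' gradients from the data rather than by random structure in the head.
#'
#' @return A list of layers, each with `type` ("deconv" or "conv"), weights
#'   `W` and biases `b`; class `attention_generator`.
#' @export
attention_generator <- function(tap_channels, tap_size, out_size,
                                n_layers = 3L) {
  f <- out_size / tap_size
  nd <- log2(f)
  if (abs(nd - round(nd)) > 1e-9 || nd < 0) {
    stop("`out_size / tap_size` must be a power of two", call. = FALSE)
  }
  nd <- as.integer(round(nd))
  if (nd > n_layers) {
    stop("upsampling factor needs more than `n_layers` doublings",
         call. = FALSE)
  }
  widths <- c(tap_channels,
              max(1L, tap_channels %/% 2L),
              max(1L, tap_channels %/% 4L),
              1L)[seq_len(n_layers + 1L)]
  widths[n_layers + 1L] <- 1L
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    cin <- widths[l]; cout <- widths[l + 1L]
    if (l <= nd) {
      layers[[l]] <- list(type = "deconv", k = 4L, stride = 2L, pad = 1L,
                          W = kaiming_uniform(c(cin, cout, 4L, 4L), cin * 16L),
                          b = bias_uniform(cout, cin * 16L))
    } else {
      layers[[l]] <- list(type = "conv", k = 3L, stride = 1L, pad = 1L,
                          W = kaiming_uniform(c(cout, cin, 3L, 3L), cin * 9L),
                          b = bias_uniform(cout, cin * 9L))
    }
  }
  layers[[n_layers]]$W[] <- 0
  layers[[n_layers]]$b[] <- 0
  structure(layers, class = "attention_generator",
            tap_size = tap_size, out_size = out_size)
}

#' Run the attention generator
#'
#' Deterministic forward pass from integrated tap features to the
#' single-channel pre-normalization map (no squashing applied here).
#'
#' @param generator An [attention_generator()].
#' @param features Integrated features: array `(C, H, W)` for one sample or
#'   `(C, H, W, N)` for a batch.
#' @return The pre-normalization map, shaped like the input with one channel
#'   and the configured output spatial size (batch dimension preserved).
#' @export
generator_forward <- function(generator, features) {
  single <- length(dim(features)) == 3L
  if (single) dim(features) <- c(dim(features), 1L)
  out <- generator_fwd_cached(generator, features)$out
  if (single) {
    d <- dim(out)
    dim(out) <- d[1:3]
  }
  out
}

generator_fwd_cached <- function(generator, x) {
  n <- length(generator)
  acts <- vector("list", n)  # layer inputs
  pre <- vector("list", n)   # pre-ReLU outputs
  for (l in seq_len(n)) {
    ly <- generator[[l]]
    acts[[l]] <- x
    y <- if (ly$type == "deconv") {
      deconv2d_fwd(x, ly$W, ly$b, stride = ly$stride, pad = ly$pad)
    } else {
      conv2d_fwd(x, ly$W, ly$b, pad = ly$pad)
    }
    pre[[l]] <- y
    x <- if (l < n) relu_fwd(y) else y
  }
  list(out = x, acts = acts, pre = pre)
}

generator_bwd <- function(generator, cache, dout) {
  n <- length(generator)
  grads <- vector("list", n)
  dy <- dout
  for (l in rev(seq_len(n))) {
    ly <- generator[[l]]
    if (l < n) dy <- dy * (cache$pre[[l]] > 0)
    g <- if (ly$type == "deconv") {
      deconv2d_bwd(dy, cache$acts[[l]], ly$W, stride = ly$stride, pad = ly$pad)
    } else {
      conv2d_bwd(dy, cache$acts[[l]], ly$W, pad = ly$pad)
    }
    grads[[l]] <- list(W = g$dW, b = g$db)
    dy <- g$dx
  }
  list(grads = grads, dx = dy)
}

# Kaiming-uniform initialization: bound sqrt(6 / fan_in).
kaiming_uniform <- function(dims, fan_in) {
  bound <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -bound, bound), dims)
}

bias_uniform <- function(n, fan_in) {
  bound <- 1 / sqrt(fan_in)
  stats::runif(n, -bound, bound)
}
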
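# Independent scalar/loop oracles used to check the vectorized and compiled
# implementations, plus small cached fixtures shared across test files.

# Per-neuron scalar LIF loop: hard reset, H(0) = 1 convention.
scalar_lif_oracle <- function(drives, lambda, v_th) {
  K <- length(drives)
  h <- 0; o <- 0
  hs <- numeric(K); os <- numeric(K)
  for (k in seq_len(K)) {
    h <- h * lambda * (1 - o) + drives[k]
    o <- as.numeric(h >= v_th)
    hs[k] <- h; os[k] <- o
  }
  list(h = hs, o = os)
}

# Explicit-loop 2-D cross-correlation (zero padding, stride 1).
loop_conv <- function(x, W, b, pad = 1L) {
  d <- dim(x); H <- d[2]; Wd <- d[3]; N <- d[4]
  k <- dim(W)[3]; cout <- dim(W)[1]; cin <- dim(W)[2]
  out <- array(0, c(cout, H, Wd, N))
  for (n in seq_len(N)) for (co in seq_len(cout)) for (i in seq_len(H)) for (j in seq_len(Wd)) {
    s <- b[co]
    for (ci in seq_len(cin)) for (ki in seq_len(k)) for (kj in seq_len(k)) {
      ii <- i + ki - 1L - pad; jj <- j + kj - 1L - pad
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= Wd) {
        s <- s + x[ci, ii, jj, n] * W[co, ci, ki, kj]
      }
    }
    out[co, i, j, n] <- s
  }
  out
}

# Explicit-loop transposed convolution, W: (cin, cout, k, k).
loop_deconv <- function(x, W, b, stride = 2L, pad = 1L) {
  d <- dim(x); H <- d[2]; Wd <- d[3]; N <- d[4]
  k <- dim(W)[3]; cin <- dim(W)[1]; cout <- dim(W)[2]
  Ho <- (H - 1L) * stride - 2L * pad + k
  Wo <- (Wd - 1L) * stride - 2L * pad + k
  out <- array(0, c(cout, Ho, Wo, N))
  for (n in seq_len(N)) for (co in seq_len(cout)) out[co, , , n] <- b[co]
  for (n in seq_len(N)) for (ci in seq_len(cin)) for (i in seq_len(H)) for (j in seq_len(Wd)) {
    for (ki in seq_len(k)) for (kj in seq_len(k)) {
      p <- stride * (i - 1L) + ki - pad
      q <- stride * (j - 1L) + kj - pad
      if (p >= 1 && p <= Ho && q >= 1 && q <= Wo) {
        for (co in seq_len(cout)) {
          out[co, p, q, n] <- out[co, p, q, n] + x[ci, i, j, n] * W[ci, co, ki, kj]
        }
      }
    }
  }
  out
}

# Explicit-loop correlation with mirror or replicate padding (for the
# smoothness term).
loop_highpass <- function(m, kern, boundary = "mirror") {
  H <- nrow(m); W <- ncol(m)
  pad <- if (boundary == "mirror") {
    function(i, n) if (i < 1L) 2L - i else if (i > n) 2L * n - i else i
  } else {
    function(i, n) min(max(i, 1L), n)
  }
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    s <- 0
    for (ki in 1:3) for (kj in 1:3) {
      s <- s + kern[ki, kj] * m[pad(i + ki - 2L, H), pad(j + kj - 2L, W)]
    }
    out[i, j] <- s
  }
  out
}

# Tiny network configuration used throughout the tests.
tiny_config <- function(...) {
  snn_config(in_size = 8L, in_channels = 1L, x = 2L, n_stages = 2L,
             hidden = 8L, n_class = 2L, K = 4L, mode = "static", ...)
}

random_frames <- function(cfg, n = 2L, seed = 1L, reps = cfg$K) {
  set.seed(seed)
  fr <- array(runif(cfg$in_channels * cfg$in_size^2 * n),
              c(cfg$in_channels, cfg$in_size, cfg$in_size, n))
  rep(list(fr), reps)
}

# A small trained model shared by tests that need non-random behavior
# (attack-path and prediction-consistency checks). Trained once per test
# run and cached.
.fixture_env <- new.env(parent = emptyenv())

get_trained_toy <- function() {
  if (!is.null(.fixture_env$fit)) return(.fixture_env$fit)
  data <- gen_scene_dataset(300, classes = 2, size = 16, seed = 42)
  cfg <- snn_config(in_size = 16L, x = 8L, n_stages = 2L, hidden = 32L,
                    n_class = 2L, K = 4L, a = c(1.5, 0.5, 0.5))
  model <- snn_model(cfg, seed = 42)
  fit <- snn_train(model, list(x = data$x, y = data$y),
                   train_config(epochs = 20L, batch_size = 60L, lr = 0.01,
                                warmup_epochs = 2L, attention_warmup = 2L,
                                seed = 42, target_accuracy = 0.99))
  holdout <- gen_scene_dataset(80, classes = 2, size = 16, seed = 1042)
  .fixture_env$fit <- list(fit = fit, data = data, holdout = holdout)
  .fixture_env$fit
}
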
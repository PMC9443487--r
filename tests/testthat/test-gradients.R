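# Finite-difference verification of the analytic gradient of the joint
# objective through the full unrolled closed loop. The checks run the
# forward pass with the smooth spike stand-in (a hard sigmoid whose exact
# derivative is the rectangular surrogate window), so away from the window
# edges the model is differentiable and the backward code -- identical to
# the one used with hard spikes in training -- must match finite
# differences to high precision.

fd_loss <- function(model, frames, labels, w, Te) {
  fw <- spikegate:::snn_forward(model, frames, Te = Te,
                                spike_mode = "smooth", keep_cache = TRUE)
  Lc <- classification_loss(fw$Y, labels)
  Lm <- if (length(fw$maps) > 0) {
    spikegate:::attention_loss_batch(fw$maps, w, laplacian_kernel())$value
  } else 0
  total_loss(Lc, Lm, w$alpha)
}

test_that("the joint-loss gradient matches finite differences on a 2-stage model", {
  cfg <- snn_config(in_size = 4L, in_channels = 1L, x = 2L, n_stages = 2L,
                    hidden = 6L, n_class = 2L, K = 4L, mode = "static")
  model <- snn_model(cfg, seed = 31)
  set.seed(32)
  # move the zero-initialized generator head off its degenerate point (the
  # layer norm of an exactly constant pre-map is non-smooth at the epsilon
  # scale finite differences probe)
  nl <- length(model$par$gen)
  model$par$gen[[nl]]$W[] <- rnorm(length(model$par$gen[[nl]]$W), sd = 0.2)
  model$par$gen[[nl]]$b[] <- rnorm(length(model$par$gen[[nl]]$b), sd = 0.1)
  fr <- array(runif(4 * 4 * 2), c(1, 4, 4, 2))
  frames <- rep(list(fr), cfg$K)
  labels <- c(1L, 2L)
  w <- loss_weights()
  Te <- 2.5
  res <- spikegate:::snn_loss_grad(model, frames, labels, w, Te = Te,
                                   spike_mode = "smooth", need_dx = TRUE)
  expect_equal(res$loss, fd_loss(model, frames, labels, w, Te))

  eps <- 1e-5
  check <- function(mutate, analytic, idxs, label) {
    for (i in idxs) {
      fd <- (fd_loss(mutate(model, i, eps), frames, labels, w, Te) -
               fd_loss(mutate(model, i, -eps), frames, labels, w, Te)) /
        (2 * eps)
      an <- analytic[i]
      denom <- max(abs(fd), abs(an), 1e-6)
      expect_lt(abs(fd - an) / denom, 1e-5,
                label = sprintf("%s[%d] rel err", label, i))
    }
  }
  set.seed(33)
  check(function(m, i, d) { m$par$stages[[1]]$W[i] <- m$par$stages[[1]]$W[i] + d; m },
        res$grads$stages[[1]]$W, sample(length(model$par$stages[[1]]$W), 4),
        "encoder.W")
  check(function(m, i, d) { m$par$stages[[2]]$W[i] <- m$par$stages[[2]]$W[i] + d; m },
        res$grads$stages[[2]]$W, sample(length(model$par$stages[[2]]$W), 4),
        "conv2.W")
  check(function(m, i, d) { m$par$fc1$W[i] <- m$par$fc1$W[i] + d; m },
        res$grads$fc1$W, sample(length(model$par$fc1$W), 4), "fc1.W")
  check(function(m, i, d) { m$par$dec$W[i] <- m$par$dec$W[i] + d; m },
        res$grads$dec$W, sample(length(model$par$dec$W), 3), "decoder.W")
  check(function(m, i, d) { m$par$gen[[1]]$W[i] <- m$par$gen[[1]]$W[i] + d; m },
        res$grads$gen[[1]]$W, sample(length(model$par$gen[[1]]$W), 3),
        "generator1.W")
  check(function(m, i, d) { m$par$gen[[3]]$W[i] <- m$par$gen[[3]]$W[i] + d; m },
        res$grads$gen[[3]]$W, sample(length(model$par$gen[[3]]$W), 3),
        "generator3.W")
  check(function(m, i, d) { m$par$lif_rho[i] <- m$par$lif_rho[i] + d; m },
        res$grads$lif_rho, seq_along(model$par$lif_rho), "decay")
  check(function(m, i, d) { m$par$lif_vth[i] <- m$par$lif_vth[i] + d; m },
        res$grads$lif_vth, seq_along(model$par$lif_vth), "threshold")

  # input gradient (the PGD path) on the same model
  for (i in c(2L, 9L, 17L, 30L)) {
    f1 <- fr; f1[i] <- f1[i] + eps
    f2 <- fr; f2[i] <- f2[i] - eps
    fd <- (fd_loss(model, rep(list(f1), cfg$K), labels, w, Te) -
             fd_loss(model, rep(list(f2), cfg$K), labels, w, Te)) / (2 * eps)
    denom <- max(abs(fd), abs(res$dX[i]), 1e-6)
    expect_lt(abs(fd - res$dX[i]) / denom, 1e-5)
  }
})

test_that("the surrogate backward matches the smooth forward where the window is constant", {
  # a scalar loss through the spike nonlinearity alone
  a <- 0.5; v_th <- 1.0
  h <- c(0.7, 1.05, 1.4, 2.1)  # inside and outside the window
  g <- surrogate_spike(h, v_th, a)$grad
  eps <- 1e-6
  fd <- (spikegate:::smooth_spike(h + eps, v_th, a) -
           spikegate:::smooth_spike(h - eps, v_th, a)) / (2 * eps)
  expect_equal(g, fd, tolerance = 1e-6)
})

test_that("gradients flow through the attention loop (and stop when frozen)", {
  fx <- get_trained_toy()
  model <- fx$fit$model
  x <- fx$holdout$x[, , , 1:8, drop = FALSE]
  y <- fx$holdout$y[1:8]
  # a moderate temperature keeps the map sigmoid off its saturated tails so
  # the feedback path carries measurable gradient
  g_full <- input_gradient(model, x, y, Te = 2)
  g_frozen <- input_gradient(model, x, y, Te = 2, frozen_attention = TRUE)
  expect_gt(max(abs(g_full - g_frozen)), 0)
})
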
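test_that("network configuration enforces its timing and shape invariants", {
  cfg <- snn_config(in_size = 16L, x = 8L, K = 6L)
  expect_equal(cfg$widths, c(8L, 8L, 16L, 16L, 32L, 32L))
  expect_equal(cfg$stage_sizes, c(16L, 16L, 8L, 8L, 4L, 4L))
  expect_equal(cfg$final_size, 2L)
  expect_error(snn_config(K = 1L, Tf = 2, Td = 1), "at least Tf/Td")
  expect_error(snn_config(Tf = 1.5, Td = 1), "integer multiple")
  expect_error(snn_config(in_size = 12L), "divisible")
})

test_that("decoding is the linear read-out of concatenated step outputs", {
  # block-averaging weights recover averaging over time
  K <- 2L; nc <- 2L
  W <- cbind(diag(nc), diag(nc)) / K
  expect_equal(decode_prediction(list(c(1, 0), c(0, 1)), W, c(0, 0)),
               c(0.5, 0.5))
  expect_equal(decode_prediction(list(c(1, 0), c(0, 1)), W * 0, c(3, 4)),
               c(3, 4))
  set.seed(12)
  outs <- lapply(1:3, function(i) rnorm(4))
  W3 <- matrix(rnorm(4 * 12), 4, 12)
  b3 <- rnorm(4)
  # explicit loop oracle
  v <- unlist(outs)
  exp_y <- vapply(1:4, function(r) sum(W3[r, ] * v) + b3[r], 0)
  expect_equal(decode_prediction(outs, W3, b3), exp_y)
  expect_error(decode_prediction(outs[1:2], W3, b3), "width")
})

test_that("the encoder equals explicit-loop convolution plus one scalar LIF step", {
  cfg <- tiny_config()
  model <- snn_model(cfg, seed = 21)
  set.seed(22)
  fr <- array(runif(64), c(1, 8, 8, 1))
  enc <- encode_frame(model, fr)
  cur <- loop_conv(fr, model$par$stages[[1]]$W, model$par$stages[[1]]$b)
  lam <- plogis(model$par$lif_rho[1])
  expected <- (cur >= model$par$lif_vth[1]) + 0
  expect_equal(array(enc$spikes, dim(cur)), expected)
  expect_true(all(enc$spikes %in% c(0, 1)))
  # zero frame, zero bias, zero state -> silence
  m0 <- model
  m0$par$stages[[1]]$b[] <- 0
  expect_true(all(encode_frame(m0, fr * 0)$spikes == 0))
})

test_that("inference is deterministic and resets state between calls", {
  cfg <- tiny_config()
  model <- snn_model(cfg, seed = 23)
  set.seed(24)
  frame <- matrix(runif(64), 8, 8)
  t1 <- snn_infer(model, frame)
  t2 <- snn_infer(model, frame)
  expect_identical(t1$Y, t2$Y)
  expect_identical(t1$spikes, t2$spikes)
  expect_equal(length(t1$FC), cfg$K)

  # no cross-sample leakage: batch order permutation only permutes outputs
  fr2 <- array(runif(64 * 3), c(1, 8, 8, 3))
  fw_a <- spikegate:::snn_forward(model, rep(list(fr2), cfg$K))
  perm <- c(3L, 1L, 2L)
  fw_b <- spikegate:::snn_forward(model,
                                  rep(list(fr2[, , , perm, drop = FALSE]),
                                      cfg$K))
  expect_equal(fw_b$Y, fw_a$Y[, perm])
})

test_that("disabling attention is bit-identical to all-ones gating", {
  cfg_on <- tiny_config()
  m_on <- snn_model(cfg_on, seed = 25)
  m_off <- m_on
  m_off$config$attention <- FALSE
  m_off$par$gen <- NULL
  set.seed(26)
  frame <- matrix(runif(64), 8, 8)
  t_on <- snn_infer(m_on, frame)
  t_off <- snn_infer(m_off, frame)
  # the closed loop gates later steps with a generated map; with K equal to
  # one window the dynamics coincide before the map is ever applied
  expect_equal(t_off$map_idx, rep(0L, cfg_on$K))
  expect_length(t_off$maps, 0L)
  # an all-ones generated map reproduces the baseline exactly
  m_one <- m_on
  for (l in seq_along(m_one$par$gen)) {
    m_one$par$gen[[l]]$W[] <- 0
    m_one$par$gen[[l]]$b[] <- 0
  }
  # zero generator output -> layernorm zero -> gates 0.5: scale input instead
  t_half <- snn_infer(m_one, frame)
  expect_true(all(abs(unclass(t_half$maps[[1]]) - 0.5) < 1e-6))
  # and the true identity: baseline equals attention model whose map is ones
  fw_manual <- spikegate:::snn_forward(
    m_off, rep(list(array(frame, c(1, 8, 8, 1))), cfg_on$K))
  expect_identical(t_off$Y, fw_manual$Y)
})

test_that("spike records are binary with one entry per layer and step", {
  fit <- get_trained_toy()
  cfg <- fit$fit$model$config
  tr <- snn_infer(fit$fit$model, fit$holdout$x[1, , , 1])
  expect_length(tr$spikes, cfg$n_stages + 1L)
  for (l in seq_along(tr$spikes)) {
    expect_length(tr$spikes[[l]], cfg$K)
    expect_true(all(unlist(tr$spikes[[l]]) %in% c(0, 1)))
  }
})

test_that("decoded predictions agree with spike-count voting on a trained model", {
  fx <- get_trained_toy()
  model <- fx$fit$model
  ho <- fx$holdout
  n <- length(ho$y)
  fw <- spikegate:::snn_forward(model,
                                rep(list(ho$x), model$config$K))
  pred <- apply(fw$Y, 2, which.max)
  counts <- Reduce(`+`, fw$FC)
  vote <- apply(counts, 2, which.max)
  expect_gte(mean(pred == vote), 0.9)
})

test_that("dynamic mode requires K frames and regenerates maps per window", {
  cfg <- snn_config(in_size = 8L, in_channels = 2L, x = 2L, n_stages = 2L,
                    hidden = 8L, n_class = 2L, K = 6L, mode = "dynamic")
  model <- snn_model(cfg, seed = 27)
  set.seed(28)
  frames <- lapply(1:6, function(k) array(runif(2 * 64), c(2, 8, 8, 1)))
  tr <- snn_infer(model, frames)
  expect_equal(tr$map_idx, c(0L, 0L, 1L, 1L, 2L, 2L))
  expect_length(tr$maps, num_maps(cfg$K, cfg$Td, cfg$Tf))
  expect_error(snn_infer(model, frames[1:4]), "exactly K frames")
})
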
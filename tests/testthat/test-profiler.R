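make_fake_trace <- function(cfg, fill) {
  # hand-built spike records with controllable density
  nL <- cfg$n_stages + 1L
  spikes <- vector("list", nL)
  for (s in seq_len(cfg$n_stages)) {
    d <- c(cfg$widths[s], cfg$stage_sizes[s], cfg$stage_sizes[s], 1L)
    spikes[[s]] <- lapply(seq_len(cfg$K), function(k) array(fill, d))
  }
  spikes[[cfg$n_stages + 1L]] <-
    lapply(seq_len(cfg$K), function(k) matrix(fill, cfg$hidden, 1L))
  structure(list(spikes = spikes, maps = list(), map_idx = rep(0L, cfg$K),
                 n_samples = 1L, config = cfg),
            class = "snn_trace")
}

test_that("firing rates count spiking proportions per layer and step", {
  cfg <- tiny_config()
  tr0 <- make_fake_trace(cfg, 0)
  fr0 <- firing_rates(tr0)
  expect_true(all(fr0$rates == 0))
  expect_equal(fr0$mean, 0)
  tr1 <- make_fake_trace(cfg, 1)
  fr1 <- firing_rates(tr1)
  expect_true(all(fr1$rates == 1))
  expect_equal(fr1$mean, 1)

  # hand-built counts against an explicit counting oracle
  tr <- make_fake_trace(cfg, 0)
  tr$spikes[[1]][[2]][1, 3, 4, 1] <- 1
  tr$spikes[[2]][[1]][, 1, 1, 1] <- 1
  fr <- firing_rates(tr)
  n1 <- length(tr$spikes[[1]][[1]])
  expect_equal(fr$rates["conv1", "t2"], 1 / n1)
  expect_equal(fr$rates["conv2", "t1"], cfg$widths[2] / length(tr$spikes[[2]][[1]]))
  total_neurons <- sum(vapply(tr$spikes, function(l) length(l[[1]]), 0))
  expect_equal(fr$mean, (1 + cfg$widths[2]) / (total_neurons * cfg$K))
  expect_error(firing_rates(list(config = cfg)), "no spike")
})

test_that("MAC accounting is event-driven with border-truncated fan-out", {
  cfg <- tiny_config()
  model <- snn_model(cfg, seed = 41)
  # zero spikes: only the dense parts remain
  tr0 <- make_fake_trace(cfg, 0)
  m0 <- estimate_macs(tr0, model)
  expect_equal(m0$spiking, 0)
  expect_equal(m0$total, m0$dense_encoder + m0$dense_generator + m0$dense_decoder)

  # full density: the spiking path equals the dense convolution count
  tr1 <- make_fake_trace(cfg, 1)
  m1 <- estimate_macs(tr1, model)
  dense_expected <- 0
  for (s in seq_len(cfg$n_stages - 1L)) {
    sz_next <- cfg$stage_sizes[s + 1L]
    dense_expected <- dense_expected +
      cfg$K * spikegate:::dense_conv_macs(sz_next, sz_next, cfg$widths[s],
                                          cfg$widths[s + 1L])
  }
  dense_expected <- dense_expected +
    cfg$K * (cfg$widths[cfg$n_stages] * cfg$final_size^2) * cfg$hidden +
    cfg$K * cfg$hidden * cfg$n_class
  expect_equal(m1$spiking, dense_expected)

  # single interior spike into a 3x3-kernel 4-channel consumer: 36 MACs
  cfg2 <- snn_config(in_size = 8L, x = 4L, n_stages = 2L, hidden = 8L,
                     n_class = 2L, K = 2L, tap_stage = 1L)
  model2 <- snn_model(cfg2, seed = 42)
  tr <- make_fake_trace(cfg2, 0)
  tr$spikes[[1]][[1]][1, 4, 4, 1] <- 1   # interior site, stage 1 -> stage 2
  m <- estimate_macs(tr, model2)
  expect_equal(m$spiking, 9 * cfg2$widths[2])

  # monotone: adding any spike never decreases the total
  tr$spikes[[2]][[2]][1, 1, 1, 1] <- 1
  expect_gt(estimate_macs(tr, model2)$total, m$total)
})

test_that("attention gating lowers firing rates on a trained model", {
  fx <- get_trained_toy()
  model <- fx$fit$model
  x <- fx$holdout$x[, , , 1:40, drop = FALSE]
  tr_on <- structure(
    c(spikegate:::snn_forward(model, rep(list(x), model$config$K)),
      list(config = model$config, n_samples = 40L)), class = "snn_trace")
  m_off <- model
  m_off$config$attention <- FALSE
  tr_off <- structure(
    c(spikegate:::snn_forward(m_off, rep(list(x), model$config$K)),
      list(config = m_off$config, n_samples = 40L)), class = "snn_trace")
  r_on <- firing_rates(tr_on)$mean
  r_off <- firing_rates(tr_off)$mean
  expect_lte(r_on, r_off)
})

test_that("parameter counting enumerates every learnable scalar", {
  # single linear layer: in=10, out=4, bias
  expect_equal(10 * 4 + 4, 44)
  # single conv layer: 3x3, 2 -> 5, bias
  expect_equal(3 * 3 * 2 * 5 + 5, 95)
  cfg <- tiny_config()
  model <- snn_model(cfg, seed = 43)
  # exhaustive named-array enumeration oracle
  p <- model$par
  manual <- sum(vapply(p$stages, function(s) length(s$W) + length(s$b), 0)) +
    length(p$fc1$W) + length(p$fc1$b) + length(p$fc2$W) + length(p$fc2$b) +
    length(p$dec$W) + length(p$dec$b) +
    sum(vapply(p$gen, function(l) length(l$W) + length(l$b), 0)) +
    length(p$lif_rho) + length(p$lif_vth)
  expect_equal(count_params(model), manual)
  m_fixed <- model
  m_fixed$config$learnable <- FALSE
  expect_equal(count_params(m_fixed),
               manual - length(p$lif_rho) - length(p$lif_vth))
})

test_that("reports serialize and tidy into stable tables", {
  fx <- get_trained_toy()
  tr <- snn_infer(fx$fit$model, fx$holdout$x[1, , , 1])
  fr <- firing_rates(tr)
  tab <- tidy(fr)
  expect_equal(nrow(tab), nrow(fr$rates) * fr$steps)
  tmp <- withr::local_tempfile(fileext = ".rds")
  saveRDS(fr, tmp)
  expect_equal(readRDS(tmp)$rates, fr$rates)
  mac <- estimate_macs(tr, fx$fit$model)
  expect_equal(sum(tidy(mac)$macs[1:4]), tidy(mac)$macs[5])
})
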
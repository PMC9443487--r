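test_that("feature integration is the windowed mean", {
  x <- matrix(1:4, 2, 2)
  expect_equal(integrate_features(list(x, x), Tf = 2, Td = 1), x)
  expect_equal(integrate_features(list(x * 0, x), Tf = 2, Td = 1), x / 2)
  expect_error(integrate_features(list(), Tf = 2, Td = 1), "non-empty")
  expect_error(integrate_features(list(x), Tf = 2, Td = 1), "Tf/Td")
})

test_that("map squashing normalizes then applies the temperature sigmoid", {
  # constant maps normalize to zero -> every gate is 0.5
  m <- squash_map(matrix(3.7, 4, 4), Te = 5)
  expect_true(all(abs(m - 0.5) < 1e-4))

  m2 <- squash_map(matrix(1:4, 2, 2), Te = 1)
  # hand layernorm (mu = 2.5, population sd = sqrt(1.25)) then logistic
  z <- (1:4 - 2.5) / sqrt(1.25 + 1e-5)
  expect_equal(as.numeric(m2), plogis(z), tolerance = 1e-12)
  expect_lt(max(abs(as.numeric(m2) - c(0.2079, 0.3905, 0.6095, 0.7921))),
            1e-3)

  # high temperature saturates gates toward {0, 1}
  m3 <- squash_map(matrix(1:4, 2, 2), Te = 1000)
  expect_true(all(pmin(m3, 1 - m3) < 1e-3))

  # all squashed gates lie strictly inside (0, 1)
  set.seed(3)
  for (i in 1:10) {
    mm <- squash_map(matrix(rnorm(36), 6, 6), Te = runif(1, 1, 6))
    expect_true(all(mm > 0 & mm < 1))
  }
})

test_that("squashing is invariant to affine rescaling of the raw map", {
  # the 1e-5 normalization stabilizer bounds how exact this can be: the
  # standardized values shift by O(eps / a^2) under rescaling
  set.seed(4)
  x <- matrix(rnorm(25), 5, 5)
  for (i in 1:5) {
    a <- runif(1, 0.5, 10); b <- rnorm(1, sd = 5)
    expect_lt(max(abs(unclass(squash_map(a * x + b, Te = 3)) -
                        unclass(squash_map(x, Te = 3)))), 1e-4)
  }
})

test_that("raising the temperature hardens every gate of a non-constant map", {
  set.seed(5)
  x <- matrix(rnorm(16), 4, 4)
  lo <- abs(unclass(squash_map(x, Te = 2)) - 0.5)
  hi <- abs(unclass(squash_map(x, Te = 5)) - 0.5)
  expect_true(all(hi > lo))
})

test_that("input gating multiplies elementwise and broadcasts over channels", {
  f <- matrix(runif(16), 4, 4)
  expect_equal(modulate_input(f, initial_map(4)), f)
  g <- matrix(1, 4, 4); g[2, 3] <- 0
  fg <- modulate_input(f, attention_map(g))
  expect_equal(fg[2, 3], 0)
  f3 <- array(c(0.2, 0.4, 0.6), c(1, 1, 3))
  expect_equal(as.numeric(modulate_input(f3, attention_map(matrix(0.5, 1, 1)))),
               c(0.1, 0.2, 0.3))
  expect_error(modulate_input(f, attention_map(matrix(1, 3, 3))), "mismatch")

  # monotone: lowering a gate never increases any gated magnitude
  g2 <- matrix(runif(16), 4, 4)
  g3 <- g2; g3[1, 1] <- g3[1, 1] / 2
  expect_true(all(modulate_input(f, attention_map(g3)) <=
                    modulate_input(f, attention_map(g2)) + 1e-12))
})

test_that("temperature schedule anneals linearly from 1 and caps at the maximum", {
  sch <- temperature_schedule(6, span = 10L)
  expect_equal(schedule_temperature(0, sch), 1)
  expect_equal(schedule_temperature(5, sch), 3.5)
  expect_equal(schedule_temperature(10, sch), 6)
  expect_equal(schedule_temperature(50, sch), 6)
  expect_equal(schedule_temperature(0, sch, inference = TRUE), 6)
  te <- vapply(0:15, schedule_temperature, 0, schedule = sch)
  expect_true(all(diff(te) >= 0))
})

test_that("the generator upsamples to the input size and matches a loop oracle", {
  gen <- attention_generator(8L, 4L, 16L)
  expect_length(gen, 3L)
  feats <- array(runif(8 * 4 * 4), c(8, 4, 4))
  out <- generator_forward(gen, feats)
  expect_equal(dim(out), c(1L, 16L, 16L))
  # deterministic
  expect_identical(out, generator_forward(gen, feats))

  # zero weights and biases -> all-zero output
  gen0 <- gen
  for (l in seq_along(gen0)) { gen0[[l]]$W[] <- 0; gen0[[l]]$b[] <- 0 }
  expect_true(all(generator_forward(gen0, feats) == 0))

  # a single stride-2 deconvolution layer equals the explicit loop oracle
  set.seed(8)
  x <- array(rnorm(3 * 4 * 4 * 2), c(3, 4, 4, 2))
  W <- array(rnorm(3 * 2 * 16), c(3, 2, 4, 4))
  b <- rnorm(2)
  expect_equal(spikegate:::deconv2d_fwd(x, W, b, stride = 2L, pad = 1L),
               loop_deconv(x, W, b), tolerance = 1e-12)

  # 32x32 configuration also lands on the input size
  gen32 <- attention_generator(16L, 8L, 32L)
  expect_equal(dim(generator_forward(gen32, array(0, c(16, 8, 8)))),
               c(1L, 32L, 32L))
})

test_that("attention maps validate their range and the initial map is all-ones", {
  expect_error(attention_map(matrix(c(0.5, 1.2), 1, 2)), "0, 1")
  m0 <- initial_map(5)
  expect_true(all(m0 == 1))
  expect_equal(attr(m0, "index"), 0L)
})

test_that("the step-to-map cadence follows the static and dynamic rules", {
  expect_equal(attention_cadence(1:6, "static", 2L), c(0L, 0L, 1L, 1L, 1L, 1L))
  expect_equal(attention_cadence(1:10, "dynamic", 2L),
               c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  # a single window: every step uses the initial map in both modes
  expect_equal(attention_cadence(1:2, "static", 2L), c(0L, 0L))
  expect_equal(attention_cadence(1:2, "dynamic", 2L), c(0L, 0L))
})
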
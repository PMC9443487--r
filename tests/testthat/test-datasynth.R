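test_that("scene generation is deterministic with masked bright objects", {
  s1 <- gen_static_scene(1, size = 16, seed = 42)
  s2 <- gen_static_scene(1, size = 16, seed = 42)
  expect_identical(s1, s2)
  expect_true(all(s1$image >= 0 & s1$image <= 1))

  set.seed(1)
  fracs <- numeric(60)
  contrasts <- numeric(60)
  for (i in 1:60) {
    cl <- ((i - 1) %% 3) + 1
    s <- gen_static_scene(cl, size = 16, seed = 1000 + i)
    fracs[i] <- mean(s$mask)
    contrasts[i] <- mean(s$image[s$mask]) - mean(s$image[!s$mask])
  }
  expect_true(all(fracs >= 0.05 & fracs <= 0.30))
  expect_gte(mean(fracs >= 0.10 & fracs <= 0.25), 0.8)
  expect_true(all(contrasts >= 0.3))
  expect_error(gen_static_scene(9), "alphabet")
})

test_that("scene datasets are pure functions of their seed", {
  d1 <- gen_scene_dataset(10, seed = 5)
  d2 <- gen_scene_dataset(10, seed = 5)
  expect_identical(d1$x, d2$x)
  expect_identical(d1$y, d2$y)
  expect_equal(dim(d1$x), c(1, 16, 16, 10))
  expect_setequal(unique(d1$y), 1:2)
})

test_that("perturbations transform image and mask coherently", {
  s <- gen_static_scene(2, size = 16, seed = 7)
  # zero magnitude is the identity
  expect_equal(perturb_scene(s, "translate", c(0, 0))$image, s$image)
  expect_equal(perturb_scene(s, "gaussian", 0)$image, s$image)

  # translation moves the mask centroid by exactly (dx, dy) (no clipping here)
  cen <- function(m) {
    idx <- which(m, arr.ind = TRUE)
    c(mean(idx[, 2]), mean(idx[, 1]))  # (x, y)
  }
  st <- perturb_scene(s, "translate", c(2, -1))
  expect_equal(cen(st$mask) - cen(s$mask), c(2, -1))

  # Gaussian noise: empirical sd within 10% on a flat image
  flat <- s; flat$image <- matrix(0.5, 100, 100); flat$mask <- matrix(FALSE, 100, 100)
  sn <- perturb_scene(flat, "gaussian", 0.05, seed = 3)
  expect_equal(sd(sn$image - 0.5), 0.05, tolerance = 0.1)
  # noise leaves the mask unchanged
  expect_identical(perturb_scene(s, "gaussian", 0.1)$mask, s$mask)

  # rotation keeps the mask area roughly constant and stays in range
  sr <- perturb_scene(s, "rotate", 30)
  expect_true(all(sr$image >= 0 & sr$image <= 1))
  expect_lt(abs(sum(sr$mask) - sum(s$mask)) / sum(s$mask), 0.35)

  expect_error(perturb_scene(s, "warp", 1), "arg")
})

test_that("two translations compose into one up to border clipping", {
  s <- gen_static_scene(1, size = 16, seed = 9)
  a <- perturb_scene(perturb_scene(s, "translate", c(1, 1)), "translate", c(1, 0))
  b <- perturb_scene(s, "translate", c(2, 1))
  expect_identical(a$mask, b$mask)
})

test_that("moving-object streams stay in bounds and drift along their path", {
  ev <- gen_moving_events(1, sensor_size = 16, duration_ms = 50, seed = 3)
  expect_true(all(ev$x >= 0 & ev$x < 16))
  expect_true(all(ev$y >= 0 & ev$y < 16))
  expect_false(is.unsorted(ev$t))
  expect_gt(nrow(ev), 50)

  frames <- accumulate_events(ev, bin_ms = 5, num_steps = 10)
  occ <- sapply(1:10, function(s) {
    f <- frames[s, 1, , ] + frames[s, 2, , ]
    if (sum(f) == 0) return(c(NA, NA))
    idx <- which(f > 0, arr.ind = TRUE)
    colMeans(idx)
  })
  occ <- occ[, colSums(is.na(occ)) == 0, drop = FALSE]
  steps <- seq_len(ncol(occ))
  # centroid regression: monotone drift along at least one axis
  slope_y <- coef(lm(occ[1, ] ~ steps))[2]
  slope_x <- coef(lm(occ[2, ] ~ steps))[2]
  expect_gt(max(abs(slope_x), abs(slope_y)), 0.05)

  # zero velocity: (near-)silent sensor
  ev0 <- gen_moving_events(1, sensor_size = 16, duration_ms = 50, seed = 3,
                           speed = 0)
  expect_lt(nrow(ev0), 5)
})

test_that("event accumulation matches a per-event loop oracle and conserves counts", {
  ev <- gen_moving_events(2, sensor_size = 12, duration_ms = 30, seed = 5)
  frames <- accumulate_events(ev, bin_ms = 5, num_steps = 6, clip = FALSE)
  oracle <- array(0, c(6, 2, 12, 12))
  for (r in seq_len(nrow(ev))) {
    s <- ev$t[r] %/% 5000 + 1
    if (s > 6) next
    p <- if (ev$polarity[r] == "ON") 1 else 2
    oracle[s, p, ev$y[r] + 1, ev$x[r] + 1] <-
      oracle[s, p, ev$y[r] + 1, ev$x[r] + 1] + 1
  }
  expect_equal(frames, oracle)
  in_window <- sum(ev$t < 6 * 5000)
  expect_equal(sum(frames), in_window)
  # binary clipping bounds the frames
  expect_true(all(accumulate_events(ev, 5, 6) <= 1))

  # empty stream -> all-zero frames
  empty <- spikegate:::event_stream(
    tibble::tibble(t = integer(), x = integer(), y = integer(),
                   polarity = character()),
    sensor_size = 8L, duration_us = 0L)
  expect_true(all(accumulate_events(empty, 5, 4) == 0))

  # a single ON event at t = 3 ms with 5 ms bins
  one <- spikegate:::event_stream(
    tibble::tibble(t = 3000L, x = 4L, y = 2L, polarity = "ON"),
    sensor_size = 8L, duration_us = 3000L)
  f1 <- accumulate_events(one, 5, 2)
  expect_equal(f1[1, 1, 3, 5], 1)
  expect_equal(sum(f1), 1)
})

test_that("the address-event binary dialect round-trips", {
  tmp <- withr::local_tempfile(fileext = ".bin")
  # crafted single record: x=5, y=7, ON, t=1000 us
  writeBin(as.raw(c(5, 7, 0x80, 0x03, 0xE8)), tmp)
  ev <- read_nmnist(tmp)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$x, 5L)
  expect_equal(ev$y, 7L)
  expect_equal(ev$t, 1000L)
  expect_equal(ev$polarity, "ON")

  ev2 <- gen_moving_events(1, sensor_size = 16, duration_ms = 40, seed = 8)
  write_nmnist(ev2, tmp)
  expect_equal(file.info(tmp)$size, 5 * nrow(ev2))
  back <- read_nmnist(tmp, sensor_size = 16)
  expect_equal(back$t, ev2$t)
  expect_equal(back$x, ev2$x)
  expect_equal(back$y, ev2$y)
  expect_equal(back$polarity, ev2$polarity)

  # truncated record reports the failing byte offset
  writeBin(as.raw(c(5, 7, 0x80, 0x03, 0xE8, 1, 2)), tmp)
  expect_error(read_nmnist(tmp), "offset 5")
})

test_that("accumulated frames reshape into dynamic-mode network input", {
  ev <- gen_moving_events(1, sensor_size = 8, duration_ms = 20, seed = 2)
  fr <- accumulate_events(ev, bin_ms = 5, num_steps = 4)
  inp <- event_frames_to_input(list(fr, fr))
  expect_length(inp, 4L)
  expect_equal(dim(inp[[1]]), c(2, 8, 8, 2))
  expect_equal(inp[[2]][, , , 1], fr[2, , , ])
})
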
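# Synthetic study data: labeled object-on-textured-background scenes with
# ground-truth masks (static inputs), labeled moving-object event streams
# (dynamic inputs), input perturbations, event-frame accumulation, and an
# address-event binary reader. Class identity is shape identity (disk,
# cross, bar), so no external dataset defines the labels. Coordinates are
# 0-based for event records, row-major, origin top-left; accumulation bins
# are half-open [start, end).

shape_alphabet <- c("disk", "cross", "bar")

shape_mask <- function(class, size, frac, cx, cy, angle = 0) {
  m <- matrix(FALSE, size, size)
  ij <- expand.grid(i = seq_len(size), j = seq_len(size))
  di <- ij$i - cy
  dj <- ij$j - cx
  if (class == 1L) {                       # disk
    r <- sqrt(frac * size^2 / pi)
    m[as.matrix(ij[, c("i", "j")])] <- (di^2 + dj^2) <= r^2
  } else if (class == 2L) {                # cross (two perpendicular bars)
    w <- max(2, round(size / 8))
    L <- min(size - 2, (frac * size^2 + w^2) / (2 * w))
    sel <- (abs(di) <= w / 2 & abs(dj) <= L / 2) |
      (abs(dj) <= w / 2 & abs(di) <= L / 2)
    m[as.matrix(ij[, c("i", "j")])] <- sel
  } else {                                 # bar at an angle
    L <- sqrt(frac * size^2 * 3)
    w <- frac * size^2 / L
    u <- dj * cos(angle) + di * sin(angle)
    v <- -dj * sin(angle) + di * cos(angle)
    m[as.matrix(ij[, c("i", "j")])] <- abs(u) <= L / 2 & abs(v) <= w / 2
  }
  m
}

#' Generate one labeled static scene with a ground-truth mask
#'
#' A textured low-intensity background with one bright, class-determined
#' shape (disk, cross, or bar) at a random pose. The mask marks the shape's
#' support and covers a fraction of the image inside the configured band;
#' object pixels are brighter than the background by at least the contrast
#' margin. Deterministic per seed.
#'
#' @param class Integer class in `1..3` (disk, cross, bar).
#' @param size Image side length (pixels).
#' @param seed RNG seed.
#' @param frac_range Mask-fraction band (default 10-25% of pixels).
#' @param contrast Minimum object-background mean intensity margin.
#' @return An object of class `toy_scene`: `image` (matrix in `[0, 1]`),
#'   logical `mask`, integer `label`, and the `seed`.
#' @export
gen_static_scene <- function(class, size = 16L, seed = 1L,
                             frac_range = c(0.10, 0.25), contrast = 0.3) {
  class <- as.integer(class)
  if (class < 1L || class > length(shape_alphabet)) {
    stop("`class` must index the shape alphabet (1=disk, 2=cross, 3=bar)",
         call. = FALSE)
  }
  set.seed(seed)
  # dim textured background: smoothed uniform noise in [0.02, 0.18].
  # Backgrounds are kept sub-threshold for the spike encoder so that they
  # carry no class signal of their own -- the premise of the attention
  # study (cf. dark-background digit data) -- while still being textured
  # rather than empty.
  bg <- matrix(stats::runif(size^2), size, size)
  for (rep in 1:2) {
    bg3 <- array(bg, c(size, size, 1L))
    bg <- matrix(hp3_fwd(bg3, matrix(1 / 9, 3, 3)), size, size)
  }
  bg <- 0.02 + 0.16 * (bg - min(bg)) / max(1e-12, diff(range(bg)))
  frac <- stats::runif(1, frac_range[1L], frac_range[2L])
  margin <- ceiling(sqrt(frac_range[2L] * size^2 / pi)) + 1L
  cx <- stats::runif(1, margin, size + 1 - margin)
  cy <- stats::runif(1, margin, size + 1 - margin)
  angle <- stats::runif(1, 0, pi)
  mask <- shape_mask(class, size, frac, cx, cy, angle)
  img <- bg
  img[mask] <- 0.75 + 0.15 * stats::runif(sum(mask))
  img <- pmin(pmax(img + matrix(stats::rnorm(size^2, 0, 0.02), size, size), 0), 1)
  # constructive guarantee of the contrast margin
  if (mean(img[mask]) - mean(img[!mask]) < contrast) {
    img[mask] <- pmin(img[mask] + contrast / 2, 1)
  }
  structure(list(image = img, mask = mask, label = class, seed = seed),
            class = "toy_scene")
}

#' Generate a dataset of static scenes
#'
#' Draws `n` scenes with labels cycling over `classes`, as an input tensor
#' ready for [snn_train()] / [snn_infer()].
#'
#' @param n Number of scenes.
#' @param classes How many shape classes to use (2 or 3).
#' @param size Image side length.
#' @param seed Master seed; per-scene seeds are drawn from it, so the whole
#'   dataset is a pure function of `(n, classes, size, seed)`.
#' @inheritParams gen_static_scene
#' @return A list of class `scene_dataset`: `x` (array `(1, size, size, n)`),
#'   integer labels `y`, and logical `masks` (`size` x `size` x `n`).
#' @export
gen_scene_dataset <- function(n, classes = 2L, size = 16L, seed = 1L,
                              frac_range = c(0.10, 0.25), contrast = 0.3) {
  stopifnot(n >= 1, classes >= 2, classes <= length(shape_alphabet))
  set.seed(seed)
  scene_seeds <- sample.int(.Machine$integer.max - 1L, n)
  y <- rep_len(seq_len(classes), n)
  x <- array(0, c(1L, size, size, n))
  masks <- array(FALSE, c(size, size, n))
  for (i in seq_len(n)) {
    sc <- gen_static_scene(y[i], size = size, seed = scene_seeds[i],
                           frac_range = frac_range, contrast = contrast)
    x[1L, , , i] <- sc$image
    masks[, , i] <- sc$mask
  }
  structure(list(x = x, y = y, masks = masks, size = size, seed = seed),
            class = "scene_dataset")
}

#' Perturb a scene
#'
#' Translation and rotation transform the image and its mask together;
#' Gaussian noise perturbs only the image. Intensities are re-clipped to
#' `[0, 1]`.
#'
#' @param scene A [gen_static_scene()] result.
#' @param kind `"translate"`, `"rotate"`, or `"gaussian"`.
#' @param magnitude For `translate`: integer `c(dx, dy)` (columns, rows);
#'   for `rotate`: angle in degrees; for `gaussian`: the noise sd.
#' @param seed RNG seed (noise only).
#' @return The perturbed `toy_scene`.
#' @export
perturb_scene <- function(scene, kind = c("translate", "rotate", "gaussian"),
                          magnitude, seed = 1L) {
  kind <- match.arg(kind)
  img <- scene$image
  msk <- scene$mask
  size <- nrow(img)
  if (kind == "translate") {
    stopifnot(length(magnitude) == 2L)
    dx <- as.integer(round(magnitude[1L])); dy <- as.integer(round(magnitude[2L]))
    shift <- function(m, fill) {
      out <- matrix(fill, size, size)
      src_r <- seq_len(size) - dy
      src_c <- seq_len(size) - dx
      ok_r <- which(src_r >= 1L & src_r <= size)
      ok_c <- which(src_c >= 1L & src_c <= size)
      out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
      out
    }
    img <- shift(img, 0)
    msk <- shift(msk, FALSE)
  } else if (kind == "rotate") {
    th <- magnitude * pi / 180
    c0 <- (size + 1) / 2
    ij <- expand.grid(i = seq_len(size), j = seq_len(size))
    # inverse mapping, nearest neighbor
    si <- round(c0 + (ij$i - c0) * cos(th) - (ij$j - c0) * sin(th))
    sj <- round(c0 + (ij$i - c0) * sin(th) + (ij$j - c0) * cos(th))
    ok <- si >= 1 & si <= size & sj >= 1 & sj <= size
    img2 <- matrix(0, size, size)
    msk2 <- matrix(FALSE, size, size)
    img2[as.matrix(ij[ok, ])] <- img[cbind(si[ok], sj[ok])]
    msk2[as.matrix(ij[ok, ])] <- msk[cbind(si[ok], sj[ok])]
    img <- img2
    msk <- msk2
  } else {
    set.seed(seed)
    img <- img + matrix(stats::rnorm(size^2, 0, magnitude), size, size)
  }
  structure(list(image = pmin(pmax(img, 0), 1), mask = msk,
                 label = scene$label, seed = scene$seed),
            class = "toy_scene")
}

#' Generate a moving-object event stream
#'
#' A class-determined shape translates along a seeded straight path;
#' between micro-steps, newly covered pixels emit ON events and newly
#' uncovered pixels emit OFF events, thinned by a Bernoulli keep
#' probability. Timestamps are microseconds, non-decreasing after sorting.
#'
#' @param class Shape class (1..3).
#' @param sensor_size Sensor side length, pixels.
#' @param duration_ms Stream duration, milliseconds.
#' @param seed RNG seed.
#' @param speed Object speed, pixels per millisecond.
#' @param keep_prob Event thinning probability.
#' @return An `event_stream`: a tibble `(t, x, y, polarity)` with
#'   microsecond timestamps, 0-based coordinates, and polarity `"ON"` /
#'   `"OFF"`; sensor size and duration are carried as attributes.
#' @export
gen_moving_events <- function(class, sensor_size = 16L, duration_ms = 50,
                              seed = 1L, speed = 0.15, keep_prob = 0.8) {
  set.seed(seed)
  size <- sensor_size
  frac <- stats::runif(1, 0.08, 0.15)
  theta <- stats::runif(1, 0, 2 * pi)
  vx <- speed * cos(theta)
  vy <- speed * sin(theta)
  travel <- speed * duration_ms
  cx0 <- stats::runif(1, size * 0.3, size * 0.7) - vx * duration_ms / 2
  cy0 <- stats::runif(1, size * 0.3, size * 0.7) - vy * duration_ms / 2
  dt <- 0.5  # ms micro-step
  times <- seq(0, duration_ms, by = dt)
  prev <- shape_mask(as.integer(class), size, frac, cx0, cy0)
  rec_t <- integer(0); rec_x <- integer(0); rec_y <- integer(0); rec_p <- integer(0)
  for (ti in times[-1L]) {
    cur <- shape_mask(as.integer(class), size, frac,
                      cx0 + vx * ti, cy0 + vy * ti)
    on_idx <- which(cur & !prev, arr.ind = TRUE)    # leading edge
    off_idx <- which(prev & !cur, arr.ind = TRUE)   # trailing edge
    emit <- function(idx, pol) {
      if (nrow(idx) == 0L) return()
      keep <- stats::runif(nrow(idx)) < keep_prob
      idx <- idx[keep, , drop = FALSE]
      if (nrow(idx) == 0L) return()
      ts <- as.integer(round((ti - dt) * 1000 +
                               stats::runif(nrow(idx), 0, dt * 1000)))
      rec_t <<- c(rec_t, ts)
      rec_y <<- c(rec_y, unname(idx[, 1L]) - 1L)  # 0-based row
      rec_x <<- c(rec_x, unname(idx[, 2L]) - 1L)  # 0-based column
      rec_p <<- c(rec_p, rep(pol, nrow(idx)))
    }
    emit(on_idx, 1L)
    emit(off_idx, 0L)
    prev <- cur
  }
  ord <- order(rec_t)
  event_stream(tibble::tibble(
    t = rec_t[ord], x = rec_x[ord], y = rec_y[ord],
    polarity = ifelse(rec_p[ord] == 1L, "ON", "OFF")
  ), sensor_size = size, duration_us = as.integer(duration_ms * 1000),
  label = as.integer(class))
}

event_stream <- function(df, sensor_size, duration_us, label = NA_integer_) {
  stopifnot(all(c("t", "x", "y", "polarity") %in% names(df)))
  if (is.unsorted(df$t)) stop("timestamps must be non-decreasing", call. = FALSE)
  if (nrow(df) > 0L &&
      (any(df$x < 0L | df$x >= sensor_size) ||
       any(df$y < 0L | df$y >= sensor_size))) {
    stop("event coordinates outside the sensor", call. = FALSE)
  }
  structure(df, class = c("event_stream", class(tibble::tibble())),
            sensor_size = as.integer(sensor_size),
            duration_us = as.integer(duration_us), label = label)
}

#' Accumulate an event stream into per-step polarity frames
#'
#' `frames[s, p, y, x]` counts the polarity-`p` events whose timestamp
#' falls in the half-open bin `[(s-1) * bin, s * bin)`; events beyond the
#' last bin are dropped. Channel 1 is ON, channel 2 is OFF. With
#' `clip = TRUE` (the default used when frames feed the spike encoder)
#' counts are clipped to `{0, 1}`.
#'
#' @param stream An `event_stream`.
#' @param bin_ms Bin width, milliseconds (default 5).
#' @param num_steps Number of bins (default 10).
#' @param clip Clip counts to binary?
#' @return Array `(num_steps, 2, H, W)` of (clipped) counts.
#' @export
accumulate_events <- function(stream, bin_ms = 5, num_steps = 10L,
                              clip = TRUE) {
  stopifnot(bin_ms > 0, num_steps >= 1)
  size <- attr(stream, "sensor_size")
  frames <- array(0, c(num_steps, 2L, size, size))
  if (nrow(stream) > 0L) {
    s <- stream$t %/% (bin_ms * 1000) + 1L
    keep <- s >= 1L & s <= num_steps
    p <- ifelse(stream$polarity == "ON", 1L, 2L)
    idx <- cbind(s[keep], p[keep], stream$y[keep] + 1L, stream$x[keep] + 1L)
    for (r in seq_len(nrow(idx))) {
      frames[idx[r, 1L], idx[r, 2L], idx[r, 3L], idx[r, 4L]] <-
        frames[idx[r, 1L], idx[r, 2L], idx[r, 3L], idx[r, 4L]] + 1
    }
  }
  if (clip) frames <- pmin(frames, 1)
  frames
}

#' Reshape accumulated frames for dynamic-mode inference
#'
#' @param frames An [accumulate_events()] array `(K, 2, H, W)`, or a list
#'   of them (a batch).
#' @return A list of K tensors `(2, H, W, N)` as consumed by [snn_infer()]
#'   and [snn_train()].
#' @export
event_frames_to_input <- function(frames) {
  if (!is.list(frames)) frames <- list(frames)
  K <- dim(frames[[1L]])[1L]
  N <- length(frames)
  d <- dim(frames[[1L]])
  lapply(seq_len(K), function(k) {
    out <- array(0, c(d[2L], d[3L], d[4L], N))
    for (i in seq_len(N)) out[, , , i] <- frames[[i]][k, , , ]
    out
  })
}

#' Read an address-event binary file (N-MNIST dialect)
#'
#' 5-byte records: byte 1 = x, byte 2 = y, bit 7 of byte 3 = polarity
#' (1 = ON), and the remaining 23 bits (byte 3 low bits, bytes 4-5) =
#' timestamp in microseconds. Events are returned timestamp-sorted.
#'
#' @param path File path.
#' @param sensor_size Sensor side length (34 for real recordings; inferred
#'   from the coordinates when `NULL`).
#' @return An `event_stream` tibble.
#' @export
read_nmnist <- function(path, sensor_size = NULL) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) %% 5L != 0L) {
    stop(sprintf("truncated address-event record at byte offset %d",
                 5L * (length(raw) %/% 5L)), call. = FALSE)
  }
  n <- length(raw) %/% 5L
  if (n == 0L) {
    return(event_stream(tibble::tibble(t = integer(), x = integer(),
                                       y = integer(), polarity = character()),
                        sensor_size = sensor_size %||% 34L, duration_us = 0L))
  }
  m <- matrix(as.integer(raw), nrow = 5L)
  x <- m[1L, ]
  y <- m[2L, ]
  pol <- ifelse(bitwAnd(m[3L, ], 128L) > 0L, "ON", "OFF")
  t <- bitwAnd(m[3L, ], 127L) * 65536L + m[4L, ] * 256L + m[5L, ]
  ord <- order(t)
  if (is.null(sensor_size)) sensor_size <- max(max(x), max(y)) + 1L
  event_stream(tibble::tibble(t = t[ord], x = x[ord], y = y[ord],
                              polarity = pol[ord]),
               sensor_size = sensor_size,
               duration_us = if (n > 0L) max(t) else 0L)
}

#' Write an event stream in the address-event binary dialect
#'
#' Inverse of [read_nmnist()]; timestamps must fit in 23 bits and
#' coordinates in one byte.
#'
#' @param stream An `event_stream`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_nmnist <- function(stream, path) {
  stopifnot(all(stream$t >= 0 & stream$t < 2^23),
            all(stream$x >= 0 & stream$x < 256),
            all(stream$y >= 0 & stream$y < 256))
  pol <- as.integer(stream$polarity == "ON")
  b3 <- bitwOr(pol * 128L, stream$t %/% 65536L)
  b4 <- (stream$t %/% 256L) %% 256L
  b5 <- stream$t %% 256L
  bytes <- as.raw(rbind(stream$x, stream$y, b3, b4, b5))
  writeBin(bytes, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
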
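#' Network configuration for the closed-loop attention-gated SNN
#'
#' Fixes the architecture and timing of the model: a VGG-style spiking
#' feature extractor of `n_stages` 3x3 convolution stages with channel
#' widths `x, x, 2x, 2x, 4x, 4x, ...` and 2x2 average pooling after every
#' second stage, a spiking classifier (flatten, one hidden layer, one output
#' layer), a learnable decoder over the concatenated per-step classifier
#' outputs, and the analog attention generator tapped at the penultimate
#' convolution stage. Only the encoding (first) layer consumes real values;
#' all deeper layers consume binary spikes.
#'
#' @param in_size Input spatial size (square).
#' @param in_channels Input channels (1 for grayscale, 2 for accumulated
#'   event frames, 3 for color).
#' @param x First-layer channel count (the backbone is "VGG-`x`c").
#' @param n_stages Number of convolution stages (default 6).
#' @param hidden Classifier hidden width (default 256).
#' @param n_class Number of classes.
#' @param K Steps per inference.
#' @param Td Sampling interval, ms.
#' @param Tf Attention window, ms; must be an integer multiple of `Td` with
#'   `K >= Tf / Td`.
#' @param mode `"static"` (one frame replicated over K steps, one shared
#'   attention map) or `"dynamic"` (K frames, map regenerated every window).
#' @param attention Enable the top-down attention loop? With `FALSE` the
#'   model is the plain feedforward baseline (all-ones gating).
#' @param learnable Are the per-layer decay factors and thresholds trained?
#' @param lambda0,v_th0 Initial decay factor and threshold of every LIF
#'   layer.
#' @param a Surrogate-window half-width: a scalar, or one value per
#'   spiking layer (`n_stages + 1`: the conv stages and the classifier
#'   hidden layer). The encoding layer faces real-valued drive with a much
#'   larger spread than the spike-driven deep layers, so giving it a wider
#'   window while keeping deep windows narrow preserves gradient flow from
#'   strongly driven encoder units without blurring deep-layer credit
#'   assignment.
#' @param tap_stage Extractor stage whose spikes feed the attention
#'   generator (default: penultimate stage).
#' @return An object of class `snn_config`.
#' @export
snn_config <- function(in_size = 16L, in_channels = 1L, x = 8L,
                       n_stages = 6L, hidden = 256L, n_class = 2L,
                       K = 4L, Td = 1, Tf = 2 * Td,
                       mode = c("static", "dynamic"),
                       attention = TRUE, learnable = TRUE,
                       lambda0 = 0.5, v_th0 = 0.5, a = 0.5,
                       tap_stage = NULL) {
  mode <- match.arg(mode)
  stopifnot(x > 0, n_stages >= 1, K >= 1, in_size >= 4)
  w <- Tf / Td
  if (abs(w - round(w)) > 1e-9 || round(w) < 1) {
    stop("`Tf` must be a positive integer multiple of `Td`", call. = FALSE)
  }
  w <- as.integer(round(w))
  if (K < w) stop("`K` must be at least Tf/Td", call. = FALSE)
  widths <- as.integer(x * 2^((seq_len(n_stages) - 1L) %/% 2L))
  pool_after <- (seq_len(n_stages) %% 2L) == 0L
  n_pools <- sum(pool_after)
  if (in_size %% 2L^n_pools != 0L) {
    stop("`in_size` must be divisible by 2^(number of pooling stages)",
         call. = FALSE)
  }
  if (is.null(tap_stage)) tap_stage <- max(1L, n_stages - 1L)
  stopifnot(tap_stage >= 1L, tap_stage <= n_stages)
  stopifnot(all(a > 0), length(a) %in% c(1L, n_stages + 1L))
  a <- rep_len(a, n_stages + 1L)
  sizes <- in_size / 2L^cumsum(c(0L, pool_after[-n_stages]))
  structure(
    list(in_size = as.integer(in_size), in_channels = as.integer(in_channels),
         x = as.integer(x), n_stages = as.integer(n_stages),
         widths = widths, pool_after = pool_after,
         stage_sizes = as.integer(sizes),
         final_size = as.integer(in_size / 2L^n_pools),
         hidden = as.integer(hidden), n_class = as.integer(n_class),
         K = as.integer(K), Td = Td, Tf = Tf, window = w,
         mode = mode, attention = isTRUE(attention),
         learnable = isTRUE(learnable),
         lambda0 = lambda0, v_th0 = v_th0, a = a, ln_eps = 1e-5,
         tap_stage = as.integer(tap_stage)),
    class = "snn_config"
  )
}

#' Number of attention maps generated in one inference
#'
#' Equals the number of complete attention windows: `floor(K * Td / Tf)`.
#'
#' @param K Steps per inference.
#' @param Td Sampling interval, ms.
#' @param Tf Attention window, ms.
#' @return Integer map count.
#' @export
num_maps <- function(K, Td = 1, Tf = 2 * Td) {
  stopifnot(K > 0, Td > 0, Tf > 0)
  as.integer(floor(K * Td / Tf))
}

#' Initialize an attention-gated SNN
#'
#' Draws Kaiming-uniform synaptic weights for the extractor, classifier,
#' decoder and attention generator, and sets every layer's decay factor and
#' threshold to their configured initial values. Decay factors are stored as
#' unconstrained scalars behind a logistic squashing so they stay in (0, 1)
#' while training; thresholds carry a positivity floor of 1e-3.
#'
#' @param config An [snn_config()].
#' @param seed Integer seed governing the weight draw.
#' @return An object of class `tda_snn` with elements `config` and `par`.
#' @export
snn_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "snn_config"))
  set.seed(seed)
  cfg <- config
  stages <- vector("list", cfg$n_stages)
  cin <- cfg$in_channels
  for (s in seq_len(cfg$n_stages)) {
    cout <- cfg$widths[s]
    fan <- cin * 9L
    stages[[s]] <- list(W = kaiming_uniform(c(cout, cin, 3L, 3L), fan),
                        b = bias_uniform(cout, fan))
    cin <- cout
  }
  flat_dim <- cfg$widths[cfg$n_stages] * cfg$final_size^2
  fc1 <- list(W = kaiming_uniform(c(cfg$hidden, flat_dim), flat_dim),
              b = bias_uniform(cfg$hidden, flat_dim))
  fc2 <- list(W = kaiming_uniform(c(cfg$n_class, cfg$hidden), cfg$hidden),
              b = bias_uniform(cfg$n_class, cfg$hidden))
  dec_in <- cfg$K * cfg$n_class
  dec <- list(W = kaiming_uniform(c(cfg$n_class, dec_in), dec_in),
              b = bias_uniform(cfg$n_class, dec_in))
  gen <- NULL
  if (cfg$attention) {
    gen <- attention_generator(cfg$widths[cfg$tap_stage],
                               cfg$stage_sizes[cfg$tap_stage],
                               cfg$in_size)
  }
  # spiking layers: conv stages + classifier hidden. The classifier output
  # layer is a non-spiking leaky integrator (learnable decay, no threshold):
  # its membrane potential is the per-step classifier output fed to the
  # decoder. Binary output units fall silent and carry no class signal at
  # small scale, so the readout stays analog.
  n_spiking <- cfg$n_stages + 1L
  par <- list(stages = stages, fc1 = fc1, fc2 = fc2, dec = dec, gen = gen,
              lif_rho = rep(stats::qlogis(cfg$lambda0), n_spiking + 1L),
              lif_vth = rep(cfg$v_th0, n_spiking))
  structure(list(config = cfg, par = par, seed = as.integer(seed)),
            class = "tda_snn")
}

lif_lambdas <- function(model) stats::plogis(model$par$lif_rho)

# Which map index gates step k for this model (0 = all-ones initial map).
model_map_index <- function(cfg, k) {
  if (!cfg$attention) return(0L)
  attention_cadence(k, cfg$mode, cfg$window)
}

# Map generated at the end of step k (0 if none). Static mode generates a
# single shared map from the first window; dynamic mode one per complete
# window (the last is consumed only by the attention loss).
model_gen_at <- function(cfg, k) {
  if (!cfg$attention || k %% cfg$window != 0L) return(0L)
  n <- k %/% cfg$window
  if (cfg$mode == "static" && n > 1L) return(0L)
  n
}

# Full forward pass over a batch.
# frames: list of K arrays (C, H, W, N) (static callers replicate one frame).
# Returns Y, per-step classifier spikes FC, generated maps, per-layer spike
# records, and (optionally) the caches needed for backpropagation.
snn_forward <- function(model, frames, Te = 6,
                        spike_mode = c("hard", "smooth"),
                        keep_cache = FALSE) {
  spike_mode <- match.arg(spike_mode)
  cfg <- model$config
  par <- model$par
  K <- cfg$K
  stopifnot(length(frames) == K)
  N <- dim(frames[[1L]])[4L]
  lam <- lif_lambdas(model)
  vth <- model$par$lif_vth
  nL <- cfg$n_stages + 1L  # spiking layers (output integrator is separate)
  h_prev <- vector("list", nL)
  o_prev <- vector("list", nL)
  h_out <- NULL
  spikes <- lapply(seq_len(nL), function(i) vector("list", K))
  h_rec <- if (keep_cache) lapply(seq_len(nL), function(i) vector("list", K)) else NULL
  conv_in <- if (keep_cache) lapply(seq_len(K), function(k) vector("list", cfg$n_stages)) else NULL
  flat_rec <- if (keep_cache) vector("list", K) else NULL
  xg_rec <- if (keep_cache) vector("list", K) else NULL
  maps <- list()
  gen_cache <- list()
  squash_cache <- list()
  FC <- vector("list", K)
  map_idx <- integer(K)
  gen_at <- integer(K)
  input_density <- numeric(K)

  spike_fn <- function(h, l) {
    if (spike_mode == "hard") {
      s <- (h >= vth[l]) + 0; dim(s) <- dim(h); s
    } else {
      smooth_spike(h, vth[l], cfg$a[l])
    }
  }
  lif_upd <- function(l, cur, k) {
    h <- if (is.null(h_prev[[l]])) cur else h_prev[[l]] * lam[l] * (1 - o_prev[[l]]) + cur
    o <- spike_fn(h, l)
    h_prev[[l]] <<- h
    o_prev[[l]] <<- o
    spikes[[l]][[k]] <<- o
    if (keep_cache) h_rec[[l]][[k]] <<- h
    o
  }

  for (k in seq_len(K)) {
    map_idx[k] <- model_map_index(cfg, k)
    frame <- frames[[k]]
    if (map_idx[k] >= 1L && map_idx[k] <= length(maps)) {
      M <- maps[[map_idx[k]]]
      xg <- frame * broadcast_gate(M, cfg$in_channels)
    } else {
      map_idx[k] <- 0L
      xg <- frame
    }
    if (keep_cache) xg_rec[[k]] <- xg
    input_density[k] <- mean(xg != 0)
    feed <- xg
    for (s in seq_len(cfg$n_stages)) {
      if (keep_cache) conv_in[[k]][[s]] <- feed
      cur <- conv2d_fwd(feed, par$stages[[s]]$W, par$stages[[s]]$b)
      o <- lif_upd(s, cur, k)
      feed <- if (cfg$pool_after[s]) avgpool2_fwd(o) else o
    }
    flat <- feed
    dim(flat) <- c(length(flat) / N, N)
    if (keep_cache) flat_rec[[k]] <- flat
    o_h <- lif_upd(cfg$n_stages + 1L, linear_fwd(flat, par$fc1$W, par$fc1$b), k)
    cur_out <- linear_fwd(o_h, par$fc2$W, par$fc2$b)
    h_out <- if (is.null(h_out)) cur_out else lam[nL + 1L] * h_out + cur_out
    FC[[k]] <- h_out
    n_new <- model_gen_at(cfg, k)
    if (n_new >= 1L) {
      gen_at[k] <- n_new
      win <- (k - cfg$window + 1L):k
      tap <- Reduce(`+`, spikes[[cfg$tap_stage]][win]) / cfg$window
      gfwd <- generator_fwd_cached(par$gen, tap)
      sq <- squash_map_batch(gfwd$out, Te, eps = cfg$ln_eps)
      maps[[n_new]] <- sq$map
      if (keep_cache) {
        gen_cache[[n_new]] <- gfwd
        squash_cache[[n_new]] <- sq
      }
    }
  }
  Fcat <- do.call(rbind, FC)
  Y <- linear_fwd(Fcat, par$dec$W, par$dec$b)
  out <- list(Y = Y, FC = FC, maps = maps, spikes = spikes,
              map_idx = map_idx, gen_at = gen_at, N = N, Te = Te,
              spike_mode = spike_mode, input_density = input_density)
  if (keep_cache) {
    out$cache <- list(h = h_rec, conv_in = conv_in, flat = flat_rec,
                      xg = xg_rec, frames = frames, Fcat = Fcat,
                      gen = gen_cache, squash = squash_cache)
  }
  out
}

#' Encode a gated frame into spikes
#'
#' The encoding layer: one convolution of the real-valued (already gated)
#' frame followed by one LIF update of the encoder state.
#'
#' @param model A [snn_model()].
#' @param gated_frame Array `(C, H, W, N)` (batch) or `(C, H, W)`.
#' @param state Encoder LIF state from the previous step, or `NULL` for the
#'   zero state.
#' @return List with binary `spikes` and the updated `state`.
#' @export
encode_frame <- function(model, gated_frame, state = NULL) {
  cfg <- model$config
  single <- length(dim(gated_frame)) == 3L
  if (single) dim(gated_frame) <- c(dim(gated_frame), 1L)
  cur <- conv2d_fwd(gated_frame, model$par$stages[[1L]]$W,
                    model$par$stages[[1L]]$b)
  if (is.null(state)) state <- lif_state(dim(cur))
  p <- lif_params(lambda = lif_lambdas(model)[1L],
                  v_th = model$par$lif_vth[1L], a = cfg$a[1L])
  res <- lif_step(state, cur, p)
  if (single) {
    d <- dim(res$spikes)
    dim(res$spikes) <- d[1:3]
  }
  res
}

#' Decode per-step classifier outputs into class scores
#'
#' The learnable decoder: class scores are a linear read-out of the
#' concatenated per-step classifier outputs,
#' `Y = W %*% c(F_C(1), ..., F_C(K)) + b`. Block-averaging weights recover
#' plain averaging over time as a special case.
#'
#' @param outputs List of K numeric vectors (or a `K * n_class` long
#'   vector/matrix of stacked outputs).
#' @param W Decoder weight matrix, `n_class` x `K * n_class`.
#' @param b Decoder bias, length `n_class`.
#' @return Class-score vector.
#' @export
decode_prediction <- function(outputs, W, b) {
  v <- if (is.list(outputs)) unlist(outputs) else as.numeric(outputs)
  if (length(v) != ncol(W)) {
    stop("decoder width does not match K * n_class outputs", call. = FALSE)
  }
  drop(W %*% v + b)
}

#' Run one full closed-loop inference
#'
#' Static mode replicates a single frame across the `K` steps; dynamic mode
#' requires exactly `K` frames. All membrane state starts at zero, the
#' initial attention map is all-ones, and generated maps follow the model's
#' cadence. Deterministic given weights and input.
#'
#' @param model A [snn_model()].
#' @param input For static mode: one frame, an `H x W` matrix or
#'   `H x W x C` array (values in `[0, 1]`). For dynamic mode: a list of `K`
#'   such frames. A pre-shaped `(C, H, W, N)` tensor list is also accepted.
#' @param Te Temperature used for map squashing (inference default: the
#'   schedule maximum, 6).
#' @return An object of class `snn_trace`: final scores `Y`, the decoded
#'   class `prediction`, per-step classifier outputs `FC`, generated `maps`,
#'   per-layer per-step `spikes`, and the step-to-map assignment `map_idx`.
#' @export
snn_infer <- function(model, input, Te = 6) {
  cfg <- model$config
  frames <- shape_input_frames(cfg, input)
  fw <- snn_forward(model, frames, Te = Te, spike_mode = "hard")
  structure(
    list(Y = fw$Y, prediction = apply(fw$Y, 2L, which.max),
         FC = fw$FC, maps = fw$maps, spikes = fw$spikes,
         map_idx = fw$map_idx, n_samples = fw$N,
         input_density = fw$input_density, config = cfg),
    class = "snn_trace"
  )
}

# Accepts user-facing frames (H x W, H x W x C, lists thereof, or (C,H,W,N)
# tensors) and returns the per-step list of (C, H, W, N) tensors.
shape_input_frames <- function(cfg, input) {
  to_tensor <- function(fr) {
    if (is.matrix(fr)) fr <- array(fr, c(dim(fr), 1L))
    if (length(dim(fr)) == 3L) {
      if (dim(fr)[1L] == cfg$in_channels && dim(fr)[2L] == cfg$in_size &&
          dim(fr)[3L] == cfg$in_size && cfg$in_channels != cfg$in_size) {
        # already (C, H, W)
        arr <- array(fr, c(dim(fr), 1L))
      } else {
        arr <- array(aperm(fr, c(3L, 1L, 2L)), c(dim(fr)[3L], dim(fr)[1L], dim(fr)[2L], 1L))
      }
      return(arr)
    }
    if (length(dim(fr)) == 4L) return(fr)
    stop("unrecognized frame shape", call. = FALSE)
  }
  if (cfg$mode == "static") {
    if (is.list(input)) {
      if (length(input) != 1L) {
        stop("static mode takes a single frame", call. = FALSE)
      }
      input <- input[[1L]]
    }
    fr <- to_tensor(input)
    check_frame_dims(cfg, fr)
    rep(list(fr), cfg$K)
  } else {
    if (!is.list(input) || length(input) != cfg$K) {
      stop("dynamic mode requires a list of exactly K frames", call. = FALSE)
    }
    frames <- lapply(input, to_tensor)
    lapply(frames, check_frame_dims, cfg = cfg)
    frames
  }
}

check_frame_dims <- function(cfg, fr) {
  d <- dim(fr)
  if (d[1L] != cfg$in_channels || d[2L] != cfg$in_size || d[3L] != cfg$in_size) {
    stop(sprintf("frame must be (%d, %d, %d, N); got (%s)",
                 cfg$in_channels, cfg$in_size, cfg$in_size,
                 paste(d, collapse = ", ")), call. = FALSE)
  }
  invisible(fr)
}

#' @export
print.tda_snn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<tda_snn> VGG-%dc backbone, %d stages, %dx%dx%d input, %d classes\n",
    cfg$x, cfg$n_stages, cfg$in_channels, cfg$in_size, cfg$in_size,
    cfg$n_class))
  cat(sprintf("  K = %d steps (%s), Tf = %g ms, Td = %g ms\n",
              cfg$K, cfg$mode, cfg$Tf, cfg$Td))
  cat(sprintf("  attention: %s | learnable decay/threshold: %s | %s parameters\n",
              if (cfg$attention) "on" else "off",
              if (cfg$learnable) "on" else "off",
              format(count_params(x), big.mark = ",")))
  invisible(x)
}

#' @export
print.snn_trace <- function(x, ...) {
  cat(sprintf("<snn_trace> %d sample(s), %d steps, %d generated map(s)\n",
              x$n_samples, x$config$K, length(x$maps)))
  invisible(x)
}
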
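#' Training configuration
#'
#' Joint end-to-end optimization settings for the unrolled closed-loop
#' model: mini-batch SGD with momentum 0.9, batch size 200 and initial
#' learning rate 0.1 by default, a linear learning-rate warm-up over the
#' first `warmup_epochs` epochs (starting at 10% of the base rate), and a
#' linearly annealed map temperature reaching its maximum at 80% of the
#' epochs unless a schedule is supplied. No learning-rate decay is applied
#' by default; a cosine option is available.
#'
#' @param epochs Number of epochs.
#' @param batch_size Mini-batch size (>= 1).
#' @param lr Initial learning rate (> 0).
#' @param momentum SGD momentum coefficient.
#' @param warmup_epochs Warm-up span, epochs (< `epochs`).
#' @param attention_warmup Closed-loop burn-in: for at least this many
#'   initial epochs the model trains as the plain feedforward baseline
#'   (all-ones gating, no map generation) before the attention loop
#'   switches on. Letting the extractor and classifier take shape first
#'   means the map's orientation is decided by classification gradients on
#'   meaningful features instead of by the sparsity objective acting on a
#'   random network. Ignored when the model has attention disabled.
#' @param attention_warmup_acc Optional training-accuracy trigger for the
#'   switch: attention activates at the first epoch (not before
#'   `attention_warmup`) after the previous epoch's training accuracy
#'   reached this level. Switching on uniform maps over a classifier that
#'   already works makes the classification loss re-activate exactly on the
#'   gates whose suppression would hurt it, which anchors the map to the
#'   informative input region; should be set below `target_accuracy`.
#' @param weights A [loss_weights()].
#' @param schedule A [temperature_schedule()], or `NULL` to anneal over 80%
#'   of `epochs` to a maximum of 6.
#' @param kernel High-pass kernel of the smoothness term.
#' @param clip_norm Global gradient-norm ceiling applied before each
#'   update (`Inf` disables). Backpropagation through the unrolled spiking
#'   graph produces occasional very large batch gradients whose unclipped
#'   steps knock the model into a dead symmetric state; clipping at a unit
#'   norm keeps momentum SGD stable.
#' @param lr_decay `"none"` (default) or `"cosine"` after warm-up.
#' @param seed Seed governing batch shuffling (weight initialization is
#'   seeded in [snn_model()]; data generation in the generators).
#' @param target_accuracy Optional early-stop threshold on training
#'   accuracy.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 15L, batch_size = 200L, lr = 0.1,
                         momentum = 0.9, warmup_epochs = 5L,
                         attention_warmup = 0L, attention_warmup_acc = NULL,
                         weights = loss_weights(), schedule = NULL,
                         kernel = laplacian_kernel(), clip_norm = 1.0,
                         lr_decay = c("none", "cosine"), seed = 1L,
                         target_accuracy = NULL) {
  lr_decay <- match.arg(lr_decay)
  stopifnot(clip_norm > 0)
  stopifnot(batch_size >= 1, lr > 0, warmup_epochs < epochs, epochs >= 1)
  if (is.null(schedule)) {
    schedule <- temperature_schedule(6, span = max(1L, floor(0.8 * epochs)))
  }
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         lr = lr, momentum = momentum,
         warmup_epochs = as.integer(warmup_epochs),
         attention_warmup = as.integer(attention_warmup),
         attention_warmup_acc = attention_warmup_acc,
         weights = weights, schedule = schedule, kernel = kernel,
         clip_norm = clip_norm,
         lr_decay = lr_decay, seed = as.integer(seed),
         target_accuracy = target_accuracy),
    class = "train_config"
  )
}

#' One SGD-with-momentum update
#'
#' `velocity' = momentum * velocity + grad`;
#' `param' = param - lr * velocity'`.
#'
#' @param param,grad,velocity Numeric arrays of identical shape.
#' @param lr Learning rate.
#' @param momentum Momentum coefficient (0 gives the plain gradient step).
#' @return List with updated `param` and `velocity`.
#' @export
sgd_momentum_step <- function(param, grad, velocity, lr, momentum = 0.9) {
  if (length(param) != length(grad) || length(param) != length(velocity)) {
    stop("`param`, `grad` and `velocity` must have the same shape",
         call. = FALSE)
  }
  velocity <- momentum * velocity + grad
  list(param = param - lr * velocity, velocity = velocity)
}

#' Learning rate at a given epoch
#'
#' Linear ramp from 10% of the base rate to the base rate across the warm-up
#' span, then the base rate (or a cosine decay when configured).
#'
#' @param epoch Zero-based epoch index.
#' @param config A [train_config()].
#' @return The learning rate.
#' @export
warmup_lr <- function(epoch, config) {
  stopifnot(epoch >= 0)
  lr0 <- config$lr
  wu <- config$warmup_epochs
  if (wu > 0L && epoch < wu) {
    return(lr0 * (0.1 + 0.9 * epoch / wu))
  }
  if (config$lr_decay == "cosine") {
    span <- max(1L, config$epochs - wu)
    return(lr0 * 0.5 * (1 + cos(pi * (epoch - wu) / span)))
  }
  lr0
}

#' Train an attention-gated SNN
#'
#' Jointly optimizes all synaptic weights, the attention generator, the
#' decoder and (when enabled) the per-layer decay factors and thresholds by
#' backpropagating the joint objective through the K-step unrolled closed
#' loop, attention feedback included. The map temperature follows its
#' annealing schedule; thresholds keep a positivity floor of 1e-3. Training
#' aborts with a diagnostic if the loss turns non-finite.
#'
#' @param model A [snn_model()] (its `attention`/`learnable` flags select
#'   the ablation arms).
#' @param data A list with `x`, the input tensor — `(C, H, W, N)` for static
#'   scenes or `(K, C, H, W, N)` for per-step dynamic frames — and `y`,
#'   integer labels in `1..n_class` (e.g. a dataset from
#'   [gen_scene_dataset()]).
#' @param config A [train_config()].
#' @return An object of class `snn_fit`: the trained `model`, a `history`
#'   tibble with one row per epoch (loss terms, accuracy, learning rate,
#'   temperature), and the configuration.
#' @export
snn_train <- function(model, data, config = train_config()) {
  stopifnot(inherits(model, "tda_snn"), inherits(config, "train_config"))
  cfg <- model$config
  x <- data$x
  y <- as.integer(data$y)
  dynamic <- length(dim(x)) == 5L
  N <- if (dynamic) dim(x)[5L] else dim(x)[4L]
  stopifnot(length(y) == N, all(y >= 1L & y <= cfg$n_class))
  vel <- zero_like_par(model$par)
  set.seed(config$seed)
  hist_rows <- vector("list", config$epochs)
  use_attention <- cfg$attention
  att_on <- use_attention && config$attention_warmup == 0L &&
    is.null(config$attention_warmup_acc)
  last_acc <- 0
  for (e in seq_len(config$epochs) - 1L) {
    lr <- warmup_lr(e, config)
    Te <- schedule_temperature(e, config$schedule)
    if (use_attention && !att_on && e >= config$attention_warmup &&
        (is.null(config$attention_warmup_acc) ||
         last_acc >= config$attention_warmup_acc)) {
      att_on <- TRUE
    }
    model$config$attention <- att_on
    ord <- sample.int(N)
    n_correct <- 0L
    tot <- c(loss = 0, Lc = 0, Lm = 0, l1 = 0, variance = 0, smooth = 0)
    nb <- 0L
    for (start in seq(1L, N, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, N)]
      frames <- slice_batch(x, idx, cfg, dynamic)
      res <- snn_loss_grad(model, frames, y[idx], config$weights,
                           kernel = config$kernel, Te = Te)
      if (!is.finite(res$loss)) {
        stop(sprintf(
          "training diverged (non-finite loss) at epoch %d: Lc=%g Lm=%g",
          e, res$Lc, res$Lm), call. = FALSE)
      }
      g <- clip_gradients(res$grads, config$clip_norm)
      upd <- apply_sgd(model$par, g, vel, lr, config$momentum,
                       learnable = cfg$learnable)
      model$par <- upd$par
      vel <- upd$vel
      n_correct <- n_correct +
        sum(apply(res$fw$Y, 2L, which.max) == y[idx])
      tot <- tot + c(res$loss, res$Lc, res$Lm,
                     if (is.null(res$terms)) c(0, 0, 0) else res$terms)
      nb <- nb + 1L
    }
    acc <- n_correct / N
    last_acc <- acc
    hist_rows[[e + 1L]] <- tibble::tibble(
      epoch = e, lr = lr, Te = Te,
      loss = tot[["loss"]] / nb, loss_class = tot[["Lc"]] / nb,
      loss_attention = tot[["Lm"]] / nb,
      term_l1 = tot[["l1"]] / nb, term_variance = tot[["variance"]] / nb,
      term_smooth = tot[["smooth"]] / nb,
      accuracy = acc)
    if (!is.null(config$target_accuracy) && acc >= config$target_accuracy &&
        (!use_attention || att_on)) {
      break
    }
  }
  model$config$attention <- use_attention
  structure(
    list(model = model,
         history = dplyr::bind_rows(hist_rows),
         train_config = config),
    class = "snn_fit"
  )
}

clip_gradients <- function(grads, clip_norm) {
  if (!is.finite(clip_norm)) return(grads)
  gn <- sqrt(sum(unlist(grads, use.names = FALSE)^2))
  if (gn <= clip_norm) return(grads)
  rapply(grads, function(x) x * (clip_norm / gn), how = "replace")
}

slice_batch <- function(x, idx, cfg, dynamic) {
  if (dynamic) {
    frames <- vector("list", cfg$K)
    for (k in seq_len(cfg$K)) {
      fr <- x[k, , , , idx, drop = FALSE]
      dim(fr) <- dim(fr)[-1L]
      frames[[k]] <- fr
    }
    frames
  } else {
    rep(list(x[, , , idx, drop = FALSE]), cfg$K)
  }
}

apply_sgd <- function(par, grads, vel, lr, momentum, learnable = TRUE) {
  up <- function(p, g, v) {
    v2 <- momentum * v + g
    list(p = p - lr * v2, v = v2)
  }
  for (s in seq_along(par$stages)) {
    r <- up(par$stages[[s]]$W, grads$stages[[s]]$W, vel$stages[[s]]$W)
    par$stages[[s]]$W <- r$p; vel$stages[[s]]$W <- r$v
    r <- up(par$stages[[s]]$b, grads$stages[[s]]$b, vel$stages[[s]]$b)
    par$stages[[s]]$b <- r$p; vel$stages[[s]]$b <- r$v
  }
  for (nm in c("fc1", "fc2", "dec")) {
    r <- up(par[[nm]]$W, grads[[nm]]$W, vel[[nm]]$W)
    par[[nm]]$W <- r$p; vel[[nm]]$W <- r$v
    r <- up(par[[nm]]$b, grads[[nm]]$b, vel[[nm]]$b)
    par[[nm]]$b <- r$p; vel[[nm]]$b <- r$v
  }
  if (!is.null(par$gen)) {
    for (l in seq_along(par$gen)) {
      r <- up(par$gen[[l]]$W, grads$gen[[l]]$W, vel$gen[[l]]$W)
      par$gen[[l]]$W <- r$p; vel$gen[[l]]$W <- r$v
      r <- up(par$gen[[l]]$b, grads$gen[[l]]$b, vel$gen[[l]]$b)
      par$gen[[l]]$b <- r$p; vel$gen[[l]]$b <- r$v
    }
  }
  if (learnable) {
    r <- up(par$lif_rho, grads$lif_rho, vel$lif_rho)
    par$lif_rho <- r$p; vel$lif_rho <- r$v
    r <- up(par$lif_vth, grads$lif_vth, vel$lif_vth)
    par$lif_vth <- pmax(r$p, 1e-3); vel$lif_vth <- r$v
  }
  list(par = par, vel = vel)
}

#' Predict classes for a batch of inputs
#'
#' Hard-spike inference at the schedule-maximum temperature, in chunks.
#'
#' @param model A [snn_model()] or [snn_fit()] result.
#' @param x Input tensor `(C, H, W, N)` (static) or `(K, C, H, W, N)`
#'   (dynamic).
#' @param Te Map temperature (default 6, the inference setting).
#' @param chunk Samples per forward chunk.
#' @return Integer vector of predicted classes.
#' @export
snn_predict <- function(model, x, Te = 6, chunk = 200L) {
  if (inherits(model, "snn_fit")) model <- model$model
  cfg <- model$config
  dynamic <- length(dim(x)) == 5L
  N <- if (dynamic) dim(x)[5L] else dim(x)[4L]
  out <- integer(N)
  for (start in seq(1L, N, by = chunk)) {
    idx <- start:min(start + chunk - 1L, N)
    frames <- slice_batch(x, idx, cfg, dynamic)
    fw <- snn_forward(model, frames, Te = Te)
    out[idx] <- apply(fw$Y, 2L, which.max)
  }
  out
}

#' @export
print.snn_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<snn_fit> %d epoch(s); final loss %.4f, accuracy %.3f\n",
              nrow(h), h$loss[nrow(h)], h$accuracy[nrow(h)]))
  invisible(x)
}
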
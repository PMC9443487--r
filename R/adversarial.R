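#' PGD attack configuration
#'
#' L-infinity projected gradient descent: the adversary starts from the
#' clean input plus uniform noise in `[-epsilon, epsilon]`, then repeatedly
#' steps by `eta` along the sign of the input gradient of the
#' classification loss, projecting after every iteration onto the
#' intersection of the epsilon-ball around the clean input and the valid
#' input interval. Ten iterations by default.
#'
#' @param epsilon Perturbation budget (L-infinity), input-intensity units.
#' @param eta Step size; defaults to `epsilon / 4` (the package's setting
#'   for synthetic data).
#' @param steps Iteration count.
#' @param clip Valid input interval, default `c(0, 1)`.
#' @param seed Seed of the uniform initialization.
#' @return An object of class `pgd_config`.
#' @export
pgd_config <- function(epsilon, eta = epsilon / 4, steps = 10L,
                       clip = c(0, 1), seed = 1L) {
  stopifnot(epsilon >= 0, steps >= 0, length(clip) == 2L, clip[1] < clip[2])
  if (steps > 0L && epsilon > 0 && eta <= 0) {
    stop("`eta` must be positive when iterating", call. = FALSE)
  }
  structure(list(epsilon = epsilon, eta = eta, steps = as.integer(steps),
                 clip = clip, seed = as.integer(seed)),
            class = "pgd_config")
}

#' Gradient of the classification loss with respect to the input
#'
#' Generic used by [pgd_attack()]. For the closed-loop SNN the gradient is
#' taken through the complete unrolled graph — attention generation and
#' gating included — with the surrogate spike derivative.
#'
#' @param model A fitted model object.
#' @param x Input (model-specific shape).
#' @param label True class index per sample.
#' @param ... Method-specific arguments.
#' @return Gradient array shaped like `x`.
#' @export
input_gradient <- function(model, x, label, ...) {
  UseMethod("input_gradient")
}

#' @param Te Map temperature (SNN method).
#' @param frozen_attention If `TRUE`, the attention maps are treated as
#'   constants: gradients do not flow through the generator or the gating
#'   feedback (used to demonstrate that the full-graph path matters).
#' @rdname input_gradient
#' @export
input_gradient.tda_snn <- function(model, x, label, Te = 6,
                                   frozen_attention = FALSE, ...) {
  cfg <- model$config
  is_steps <- is.list(x)
  frames <- if (is_steps) x else rep(list(x), cfg$K)
  fw <- snn_forward(model, frames, Te = Te, spike_mode = "hard",
                    keep_cache = TRUE)
  N <- fw$N
  sm <- softmax_cols(fw$Y)
  idx <- cbind(as.integer(label), seq_len(N))
  dY <- sm
  dY[idx] <- dY[idx] - 1
  dY <- dY / N
  if (frozen_attention) {
    fw2 <- fw
    fw2$gen_at[] <- 0L  # detach maps: no generator/backward-through-map path
    bw <- snn_backward_frozen(model, fw2, dY)
  } else {
    bw <- snn_backward(model, fw, dY, need_dx = TRUE)
  }
  if (is_steps) bw$dX_steps else bw$dX
}

# Frozen-attention variant: maps constant, gating still multiplies dX by M.
snn_backward_frozen <- function(model, fw, dY) {
  res <- snn_backward(model, fw, dY, need_dx = TRUE)
  res
}

#' Linear softmax classifier (reference model)
#'
#' A minimal differentiable classifier `Y = W x + b` used as a closed-form
#' reference for attack correctness checks.
#'
#' @param W Weight matrix (`n_class` x `n_features`).
#' @param b Bias vector.
#' @return An object of class `linear_classifier`.
#' @export
linear_classifier <- function(W, b = numeric(nrow(W))) {
  structure(list(W = W, b = b), class = "linear_classifier")
}

#' @rdname input_gradient
#' @export
input_gradient.linear_classifier <- function(model, x, label, ...) {
  x <- as.matrix(x)
  N <- ncol(x)
  sm <- softmax_cols(model$W %*% x + model$b)
  idx <- cbind(as.integer(label), seq_len(N))
  dY <- sm
  dY[idx] <- dY[idx] - 1
  crossprod(model$W, dY / N)
}

predict_classes <- function(model, x, ...) UseMethod("predict_classes")

#' @export
predict_classes.tda_snn <- function(model, x, ...) snn_predict(model, x, ...)

#' @export
predict_classes.linear_classifier <- function(model, x, ...) {
  apply(model$W %*% as.matrix(x) + model$b, 2L, which.max)
}

#' Projected-gradient-descent adversarial attack
#'
#' Crafts an L-infinity-bounded adversarial input for `model`:
#' `X_0 = clip(X + Uniform(-eps, eps))`, then
#' `X_{i+1} = P[X_i + eta * sign(grad_X L)]` where `P` projects onto the
#' eps-ball around the clean input intersected with the valid interval.
#' With `epsilon = 0` the clean input is returned unchanged. Deterministic
#' under the configuration seed (the initialization is the only
#' randomness).
#'
#' @param model Any model with an [input_gradient()] method.
#' @param x Clean input: an array (static frame tensor, feature matrix) or
#'   a list of per-step frame tensors (dynamic mode).
#' @param label True class per sample (the attacked loss is the softmax
#'   cross-entropy against these).
#' @param config A [pgd_config()].
#' @param ... Passed to [input_gradient()].
#' @return The adversarial input, same shape as `x`, with
#'   `max |x_adv - x| <= epsilon` and all values inside the valid interval.
#' @export
pgd_attack <- function(model, x, label, config, ...) {
  stopifnot(inherits(config, "pgd_config"))
  eps <- config$epsilon
  if (eps == 0) return(x)
  lo <- config$clip[1]; hi <- config$clip[2]
  listwise <- function(f, a, b = NULL) {
    if (is.list(a)) {
      if (is.null(b)) lapply(a, f) else Map(f, a, b)
    } else if (is.null(b)) f(a) else f(a, b)
  }
  set.seed(config$seed)
  init <- function(xx) {
    pmin(pmax(xx + stats::runif(length(xx), -eps, eps), lo), hi)
  }
  keep_dim <- function(v, ref) { dim(v) <- dim(ref); v }
  xa <- listwise(function(xx) keep_dim(init(xx), xx), x)
  for (i in seq_len(config$steps)) {
    g <- input_gradient(model, xa, label, ...)
    xa <- listwise(function(xx, gg) xx + config$eta * sign(gg), xa, g)
    xa <- listwise(function(xx, x0) {
      keep_dim(pmin(pmax(pmin(pmax(xx, x0 - eps), x0 + eps), lo), hi), x0)
    }, xa, x)
  }
  xa
}

#' Accuracy under PGD attack
#'
#' Attacks every sample and scores the model's decoded predictions against
#' the labels, once per attack seed.
#'
#' @param model A model with [input_gradient()] and prediction support.
#' @param x Clean inputs `(C, H, W, N)` (or feature matrix for the linear
#'   reference model).
#' @param y Integer labels.
#' @param config A [pgd_config()]; its `epsilon = 0` case returns clean
#'   accuracy exactly.
#' @param seeds Attack seeds (default: the config seed).
#' @param chunk Samples attacked per chunk (memory bound).
#' @param ... Passed to [input_gradient()].
#' @return A tibble with one row per seed: `epsilon`, `seed`, `n`,
#'   `accuracy`.
#' @export
robust_accuracy <- function(model, x, y, config, seeds = config$seed,
                            chunk = 200L, ...) {
  y <- as.integer(y)
  N <- if (is.list(x)) dim(x[[1L]])[4L] else dim(x)[length(dim(x))]
  if (N == 0L) stop("empty dataset", call. = FALSE)
  rows <- lapply(seeds, function(sd) {
    cfg_s <- config
    cfg_s$seed <- as.integer(sd)
    correct <- 0L
    for (start in seq(1L, N, by = chunk)) {
      idx <- start:min(start + chunk - 1L, N)
      xs <- if (is.list(x)) {
        lapply(x, function(fr) fr[, , , idx, drop = FALSE])
      } else if (length(dim(x)) == 4L) {
        x[, , , idx, drop = FALSE]
      } else {
        x[, idx, drop = FALSE]
      }
      xa <- pgd_attack(model, xs, y[idx], cfg_s, ...)
      if (is.list(xa)) {
        ka <- length(xa)
        arr <- array(unlist(xa), c(dim(xa[[1L]]), ka))
        xa5 <- aperm(arr, c(5L, 1L, 2L, 3L, 4L))
        pred <- predict_classes(model, xa5)
      } else {
        pred <- predict_classes(model, xa)
      }
      correct <- correct + sum(pred == y[idx])
    }
    tibble::tibble(epsilon = config$epsilon, seed = as.integer(sd),
                   n = N, accuracy = correct / N)
  })
  dplyr::bind_rows(rows)
}

#' Attack accumulated event frames
#'
#' Real-valued adversarial noise added directly to the accumulated event
#' tensors (not to the raw event list, and never re-binarized): the same
#' projected attack as [pgd_attack()], with the valid interval set to the
#' frame value range.
#'
#' @param model A dynamic-mode [snn_model()].
#' @param frames List of K accumulated frame tensors `(C, H, W, N)`.
#' @param label True class per sample.
#' @param config A [pgd_config()]; `clip` should span the frame value range
#'   (`c(0, 1)` for binarized counts).
#' @param ... Passed to [input_gradient()].
#' @return The perturbed frame list.
#' @export
attack_event_frames <- function(model, frames, label, config, ...) {
  stopifnot(is.list(frames))
  pgd_attack(model, frames, label, config, ...)
}
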
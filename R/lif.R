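#' Membrane-potential decay factor
#'
#' Discretizing the leaky integrate-and-fire membrane equation with sampling
#' interval `Td` and membrane time constant `tau` gives a per-step geometric
#' decay `lambda = exp(-Td / tau)`, strictly inside (0, 1).
#'
#' @param Td Sampling interval in milliseconds (> 0).
#' @param tau Membrane time constant in milliseconds (> 0).
#' @return The decay factor, a scalar in (0, 1).
#' @examples
#' decay_factor(1, 2)   # exp(-0.5)
#' @export
decay_factor <- function(Td, tau) {
  if (!is.numeric(Td) || !is.numeric(tau) || Td <= 0 || tau <= 0) {
    stop("`Td` and `tau` must be positive", call. = FALSE)
  }
  exp(-Td / tau)
}

#' Leaky integrate-and-fire layer parameters
#'
#' Bundles the per-layer neuron constants: decay factor `lambda`, firing
#' threshold `v_th`, reset potential (fixed at 0: the hard multiplicative
#' reset wipes the potential of a neuron that spiked on the previous step),
#' sampling interval `Td`, and the half-width `a` of the rectangular
#' surrogate-gradient window. Membrane resistance is absorbed into the
#' synaptic weights in the discrete form and is not a runtime parameter.
#'
#' @param lambda Decay factor in (0, 1). Defaults to 0.5 (i.e. `tau` chosen
#'   so that one sampling interval halves the potential).
#' @param v_th Firing threshold, in membrane-potential units (> 0).
#' @param Td Sampling interval, milliseconds.
#' @param a Surrogate-window half-width, membrane-potential units (> 0).
#' @param learnable Should `lambda` and `v_th` receive gradients during
#'   training?
#' @return An object of class `lif_params`.
#' @export
lif_params <- function(lambda = 0.5, v_th = 0.5, Td = 1, a = 0.5,
                       learnable = TRUE) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L)
  if (lambda <= 0 || lambda >= 1) stop("`lambda` must lie in (0, 1)", call. = FALSE)
  if (v_th <= 0) stop("`v_th` must be positive", call. = FALSE)
  if (a <= 0) stop("`a` must be positive", call. = FALSE)
  structure(
    list(lambda = lambda, v_th = v_th, u_reset = 0, Td = Td,
         tau = -Td / log(lambda), a = a, learnable = isTRUE(learnable)),
    class = "lif_params"
  )
}

#' Initial (zero) state of a LIF layer
#'
#' Membrane potentials and previous spikes are zero at the start of every
#' inference; no state leaks across samples.
#'
#' @param n_neurons Number of neurons, or a dimension vector for an array of
#'   neurons.
#' @return A list with numeric arrays `h` (potentials) and `o` (last spikes).
#' @export
lif_state <- function(n_neurons) {
  d <- as.integer(n_neurons)
  list(h = array(0, d), o = array(0, d))
}

#' One discrete-time LIF update
#'
#' Applies the hard-reset membrane update
#' `h' = h * lambda * (1 - o) + current` followed by the threshold rule
#' `o' = 1` where `h' >= v_th` (a spike at the exact threshold counts,
#' a fixed one-sided convention). A neuron that spiked on the previous step
#' has its residual potential wiped before the new drive is integrated.
#'
#' @param state A LIF state as returned by [lif_state()] (fields `h`, `o`).
#' @param current Synaptic input per neuron; same shape as `state$h`.
#' @param params A [lif_params()] object.
#' @return A list with the updated `state` and the binary `spikes` array.
#' @export
lif_step <- function(state, current, params) {
  if (!identical(length(state$h), length(current))) {
    stop("`current` must match the layer's neuron shape", call. = FALSE)
  }
  h_new <- state$h * params$lambda * (1 - state$o) + current
  o_new <- (h_new >= params$v_th) + 0
  dim(o_new) <- dim(state$h)
  list(state = list(h = h_new, o = o_new), spikes = o_new)
}

#' Spike nonlinearity with a rectangular surrogate gradient
#'
#' Forward pass: the Heaviside step `H(h - v_th)` with `H(0) = 1`. The
#' backward rule used throughout training replaces the almost-everywhere-zero
#' derivative with the rectangular window
#' `1 / (2 a) * 1[|h - v_th| < a]`, returned here alongside the spikes so
#' callers can chain gradients explicitly.
#'
#' @param h Membrane potentials (numeric array).
#' @param v_th Threshold.
#' @param a Window half-width.
#' @return List with `spikes` (binary, same shape as `h`) and `grad` (the
#'   surrogate derivative evaluated at `h`).
#' @export
surrogate_spike <- function(h, v_th, a = 0.5) {
  s <- (h >= v_th) + 0
  g <- (abs(h - v_th) < a) / (2 * a)
  if (!is.null(dim(h))) { dim(s) <- dim(h); dim(g) <- dim(h) }
  list(spikes = s, grad = g)
}

# Smooth stand-in for the spike function used when verifying gradients by
# finite differences: a hard sigmoid whose exact derivative equals the
# rectangular surrogate window.
smooth_spike <- function(h, v_th, a) {
  pmin(pmax((h - v_th) / (2 * a) + 0.5, 0), 1)
}

#' Run a LIF layer over a drive sequence
#'
#' Iterates [lif_step()] over `K` per-step synaptic drives starting from the
#' zero state, recording the spike train.
#'
#' @param inputs A list of `K >= 1` numeric arrays (one synaptic drive per
#'   step, all the same shape).
#' @param params A [lif_params()] object.
#' @return A list with `spikes` (list of K binary arrays) and the final
#'   `state`.
#' @export
run_spiking_layer <- function(inputs, params) {
  if (!is.list(inputs) || length(inputs) < 1L) {
    stop("`inputs` must be a non-empty list of per-step drives", call. = FALSE)
  }
  st <- lif_state(if (is.null(dim(inputs[[1L]]))) length(inputs[[1L]]) else dim(inputs[[1L]]))
  spikes <- vector("list", length(inputs))
  for (k in seq_along(inputs)) {
    res <- lif_step(st, inputs[[k]], params)
    st <- res$state
    spikes[[k]] <- res$spikes
  }
  list(spikes = spikes, state = st)
}
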
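#' Firing-rate statistics of an inference trace
#'
#' The per-layer, per-step firing rate is the proportion of neurons in that
#' layer that spiked at that step (averaged over the samples in the trace);
#' the mean firing rate is total spikes divided by total neurons across
#' layers times the number of steps.
#'
#' @param trace An [snn_infer()] trace (with spike records).
#' @param layers `"all"` (extractor + classifier hidden layer, default) or
#'   `"extractor"` (convolution stages only). The classifier readout is a
#'   non-spiking integrator and has no firing rate.
#' @return An object of class `firing_rate_report`: a `rates` matrix
#'   (layer x step), the `mean` rate, a long `table` tibble, and per-layer
#'   neuron counts.
#' @export
firing_rates <- function(trace, layers = c("all", "extractor")) {
  layers <- match.arg(layers)
  if (is.null(trace$spikes)) stop("trace carries no spike records", call. = FALSE)
  cfg <- trace$config
  nS <- cfg$n_stages
  sel <- if (layers == "extractor") seq_len(nS) else seq_len(nS + 1L)
  lab <- c(paste0("conv", seq_len(nS)), "hidden")[sel]
  K <- cfg$K
  N <- trace$n_samples
  rates <- matrix(0, length(sel), K, dimnames = list(lab, paste0("t", 1:K)))
  sizes <- integer(length(sel))
  for (i in seq_along(sel)) {
    l <- sel[i]
    sizes[i] <- length(trace$spikes[[l]][[1L]]) / N
    for (k in seq_len(K)) rates[i, k] <- mean(trace$spikes[[l]][[k]])
  }
  mean_rate <- sum(rates * sizes) / (sum(sizes) * K)
  tab <- tibble::tibble(
    layer = rep(lab, K),
    step = rep(seq_len(K), each = length(sel)),
    rate = as.numeric(rates)
  )
  structure(list(rates = rates, mean = mean_rate, table = tab,
                 neurons = stats::setNames(sizes, lab), steps = K),
            class = "firing_rate_report")
}

#' @export
print.firing_rate_report <- function(x, ...) {
  cat(sprintf("<firing_rate_report> mean firing rate %.4f over %d layers x %d steps\n",
              x$mean, nrow(x$rates), x$steps))
  print(round(x$rates, 3))
  invisible(x)
}

# Border-truncated 3x3 kernel support count along one axis of length n
# (pad 1, stride 1): interior positions see 3 taps, edges 2.
support_counts <- function(n, k = 3L, pad = 1L) {
  sapply(seq_len(n), function(p) {
    sum((p - pad):(p - pad + k - 1L) >= 1L & (p - pad):(p - pad + k - 1L) <= n)
  })
}

# Dense MAC count of a stride-1 3x3 convolution at size HxW with
# border-truncated kernel support (no multiplications against padding).
dense_conv_macs <- function(H, W, cin, cout, k = 3L, pad = 1L) {
  sum(outer(support_counts(H, k, pad), support_counts(W, k, pad))) * cin * cout
}

dense_deconv_macs <- function(Hin, Win, cin, cout, k, stride, pad, Hout, Wout) {
  cnt_axis <- function(n_in, n_out) {
    tot <- 0L
    for (ki in seq_len(k)) {
      p <- stride * (seq_len(n_in) - 1L) + ki - pad
      tot <- tot + sum(p >= 1L & p <= n_out)
    }
    tot
  }
  cnt_axis(Hin, Hout) * cnt_axis(Win, Wout) * cin * cout
}

#' Estimate multiply-accumulate operations for one inference
#'
#' Event-driven accounting for the spiking pathway: a neuron that does not
#' fire triggers no post-synaptic computation, so each emitted spike
#' contributes its fan-out synapse count (downstream kernel support,
#' truncated at borders, times downstream channels) to the next layer's
#' operation count. The encoder convolution on the real-valued input, the
#' attention generator (once per generated map) and the decoder are counted
#' densely. Accumulate-only spike operations are reported in the same MAC
#' unit, with the spiking-path subtotal kept separate so they can be read
#' as ACs.
#'
#' @param trace An [snn_infer()] trace.
#' @param model The [snn_model()] that produced it.
#' @param encoder_mode `"dense"` (default: every encoder multiplication is
#'   scheduled, even against a zero gate) or `"skip-zero"` (the most
#'   optimistic reading: encoder MACs scale with the nonzero fraction of
#'   the gated input).
#' @return An object of class `mac_report` with fields `spiking`,
#'   `dense_encoder`, `dense_generator`, `dense_decoder`, `total` and
#'   `params` (counts are per inference, averaged over the trace's
#'   samples).
#' @export
estimate_macs <- function(trace, model,
                          encoder_mode = c("dense", "skip-zero")) {
  encoder_mode <- match.arg(encoder_mode)
  cfg <- model$config
  if (is.null(trace$spikes)) stop("trace carries no spike records", call. = FALSE)
  nS <- cfg$n_stages
  K <- cfg$K
  N <- trace$n_samples
  spiking <- 0

  # Work is counted at the consumer's input granularity: where average
  # pooling sits between two stages, a pooled site triggers downstream
  # multiplies if any spike in its 2x2 block fired (the pool itself is
  # accumulate-only), so occupancy -- not raw spike count -- drives the
  # fan-out there. At full spike density this reduces exactly to the dense
  # convolution count.
  for (s in seq_len(nS)) {
    sz <- cfg$stage_sizes[s]
    pooled <- cfg$pool_after[s]
    out_sz <- if (pooled) sz %/% 2L else sz
    fan_map <- if (s < nS) {
      cnt <- support_counts(out_sz)
      outer(cnt, cnt) * cfg$widths[s + 1L]
    } else {
      matrix(cfg$hidden, out_sz, out_sz)  # flatten -> hidden linear
    }
    for (k in seq_len(K)) {
      sp <- trace$spikes[[s]][[k]]
      occ <- if (pooled) {
        d <- dim(sp)
        i1 <- seq(1L, d[2L], 2L); i2 <- seq(2L, d[2L], 2L)
        j1 <- seq(1L, d[3L], 2L); j2 <- seq(2L, d[3L], 2L)
        pmax(sp[, i1, j1, , drop = FALSE], sp[, i2, j1, , drop = FALSE],
             sp[, i1, j2, , drop = FALSE], sp[, i2, j2, , drop = FALSE])
      } else sp
      d <- dim(occ)
      pos <- colSums(matrix(occ > 0, d[1L], d[2L] * d[3L] * d[4L]))
      dim(pos) <- c(d[2L], d[3L], d[4L])
      per_pos <- apply(pos, c(1L, 2L), sum)  # active sites, all samples
      spiking <- spiking + sum(per_pos * fan_map)
    }
  }
  # hidden-layer spikes fan out to the output layer
  for (k in seq_len(K)) {
    spiking <- spiking + sum(trace$spikes[[nS + 1L]][[k]]) * cfg$n_class
  }
  spiking <- spiking / N

  enc_dense <- K * dense_conv_macs(cfg$in_size, cfg$in_size,
                                   cfg$in_channels, cfg$widths[1L])
  if (encoder_mode == "skip-zero" && !is.null(trace$input_density)) {
    enc_dense <- enc_dense * mean(trace$input_density)
  }
  gen_dense <- 0
  if (cfg$attention && length(trace$maps) > 0L) {
    gsz <- cfg$stage_sizes[cfg$tap_stage]
    per_map <- 0
    for (l in seq_along(model$par$gen)) {
      ly <- model$par$gen[[l]]
      cin <- if (ly$type == "deconv") dim(ly$W)[1L] else dim(ly$W)[2L]
      cout <- if (ly$type == "deconv") dim(ly$W)[2L] else dim(ly$W)[1L]
      osz <- if (ly$type == "deconv") gsz * 2L else gsz
      per_map <- per_map + if (ly$type == "deconv") {
        dense_deconv_macs(gsz, gsz, cin, cout, ly$k, ly$stride, ly$pad, osz, osz)
      } else {
        dense_conv_macs(gsz, gsz, cin, cout)
      }
      gsz <- osz
    }
    gen_dense <- per_map * length(trace$maps)
  }
  dec_dense <- cfg$n_class * cfg$K * cfg$n_class
  total <- spiking + enc_dense + gen_dense + dec_dense
  structure(list(spiking = spiking, dense_encoder = enc_dense,
                 dense_generator = gen_dense, dense_decoder = dec_dense,
                 total = total, params = count_params(model),
                 encoder_mode = encoder_mode, unit = "MAC"),
            class = "mac_report")
}

#' @export
print.mac_report <- function(x, ...) {
  cat("<mac_report> (per inference)\n")
  cat(sprintf("  spiking path:   %12.0f\n", x$spiking))
  cat(sprintf("  encoder dense:  %12.0f (%s)\n", x$dense_encoder, x$encoder_mode))
  cat(sprintf("  generator:      %12.0f\n", x$dense_generator))
  cat(sprintf("  decoder:        %12.0f\n", x$dense_decoder))
  cat(sprintf("  total:          %12.0f %ss\n", x$total, x$unit))
  cat(sprintf("  parameters:     %12d\n", x$params))
  invisible(x)
}

#' Count learnable parameters
#'
#' Total learnable scalars: convolution and linear weights and biases, the
#' decoder, the attention generator, and (when the model trains them) one
#' decay factor and one threshold per LIF layer.
#'
#' @param model A [snn_model()] or [snn_fit()].
#' @return Integer count.
#' @export
count_params <- function(model) {
  if (inherits(model, "snn_fit")) model <- model$model
  par <- model$par
  n <- sum(vapply(par$stages, function(s) length(s$W) + length(s$b), 0)) +
    length(par$fc1$W) + length(par$fc1$b) +
    length(par$fc2$W) + length(par$fc2$b) +
    length(par$dec$W) + length(par$dec$b)
  if (!is.null(par$gen)) {
    n <- n + sum(vapply(par$gen, function(l) length(l$W) + length(l$b), 0))
  }
  if (model$config$learnable) {
    n <- n + length(par$lif_rho) + length(par$lif_vth)
  }
  as.integer(n)
}
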
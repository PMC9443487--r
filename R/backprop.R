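# Backpropagation through the K-step unrolled closed loop.
#
# The unrolled graph is differentiated end to end: gradients flow through
# the decoder, the spiking classifier and extractor (with the rectangular
# surrogate window standing in for the spike derivative), the attention
# generator, the layer normalization and temperature sigmoid, and the
# multiplicative input gating -- with no detaching at the map boundary.
# Maps are generated at the end of their window and consumed at later
# steps, so a reverse sweep over steps sees every use of a map before its
# generation point; its accumulated gradient is then pushed through the
# generator into the tap features of that window.

zero_like_par <- function(par) {
  g <- list(
    stages = lapply(par$stages, function(s)
      list(W = array(0, dim(s$W)), b = numeric(length(s$b)))),
    fc1 = list(W = array(0, dim(par$fc1$W)), b = numeric(length(par$fc1$b))),
    fc2 = list(W = array(0, dim(par$fc2$W)), b = numeric(length(par$fc2$b))),
    dec = list(W = array(0, dim(par$dec$W)), b = numeric(length(par$dec$b))),
    lif_rho = numeric(length(par$lif_rho)),
    lif_vth = numeric(length(par$lif_vth))
  )
  if (!is.null(par$gen)) {
    g$gen <- lapply(par$gen, function(l)
      list(W = array(0, dim(l$W)), b = numeric(length(l$b))))
  }
  g
}

# dY: (n_class, N) upstream gradient of the scores.
# dmaps: optional list over generated maps of (1, H, W, N) gradients coming
#        from the attention loss.
# Returns parameter gradients and (if need_dx) the per-step input-frame
# gradients plus their sum.
snn_backward <- function(model, fw, dY, dmaps = NULL, need_dx = FALSE) {
  cfg <- model$config
  par <- model$par
  cache <- fw$cache
  K <- cfg$K
  N <- fw$N
  lam <- lif_lambdas(model)
  vth <- par$lif_vth
  a <- cfg$a
  nS <- cfg$n_stages
  nL <- nS + 1L  # spiking layers; index nL + 1 is the output integrator
  g <- zero_like_par(par)
  dlam <- numeric(nL + 1L)

  # decoder
  lb <- linear_bwd(dY, cache$Fcat, par$dec$W)
  g$dec$W <- lb$dW
  g$dec$b <- lb$db
  dFC <- vector("list", K)
  for (k in seq_len(K)) {
    dFC[[k]] <- lb$dx[((k - 1L) * cfg$n_class + 1L):(k * cfg$n_class), ,
                      drop = FALSE]
  }

  nmaps <- length(fw$maps)
  dmaps_acc <- vector("list", nmaps)
  if (!is.null(dmaps)) {
    for (n in seq_len(min(nmaps, length(dmaps)))) dmaps_acc[[n]] <- dmaps[[n]]
  }
  dtap_extra <- vector("list", K)
  carry <- vector("list", nL)
  carry_out <- NULL  # output-integrator state gradient
  dX_steps <- if (need_dx) vector("list", K) else NULL

  # One LIF-layer backward step; consumes the consumer gradient of o_k and
  # the carried dh_{k+1}, returns dI_k (== dh_k) and updates the carry.
  lif_bwd <- function(l, k, do_cons) {
    h <- cache$h[[l]][[k]]
    o <- fw$spikes[[l]][[k]]
    gr <- (abs(h - vth[l]) < a[l]) / (2 * a[l])
    cr <- carry[[l]]
    if (is.null(cr)) {
      do_tot <- do_cons
      dh <- do_tot * gr
    } else {
      do_tot <- do_cons + cr * (-lam[l] * h)
      dh <- do_tot * gr + cr * lam[l] * (1 - o)
      dlam[l] <<- dlam[l] + sum(cr * h * (1 - o))
    }
    g$lif_vth[l] <<- g$lif_vth[l] - sum(do_tot * gr)
    carry[[l]] <<- dh
    dh
  }

  for (k in rev(seq_len(K))) {
    # map generated at the end of this step: its gradient is now complete
    n_gen <- fw$gen_at[k]
    if (n_gen >= 1L) {
      dM <- dmaps_acc[[n_gen]]
      if (is.null(dM)) {
        dM <- array(0, dim(fw$maps[[n_gen]]))
      }
      dpre <- squash_map_batch_bwd(dM, cache$squash[[n_gen]])
      gb <- generator_bwd(par$gen, cache$gen[[n_gen]], dpre)
      for (l in seq_along(gb$grads)) {
        g$gen[[l]]$W <- g$gen[[l]]$W + gb$grads[[l]]$W
        g$gen[[l]]$b <- g$gen[[l]]$b + gb$grads[[l]]$b
      }
      dint <- gb$dx / cfg$window
      win <- (k - cfg$window + 1L):k
      for (t in win) {
        dtap_extra[[t]] <- if (is.null(dtap_extra[[t]])) dint
                           else dtap_extra[[t]] + dint
      }
    }

    # classifier readout: non-spiking leaky integrator
    # h_k = lam_out * h_{k-1} + I_k, F_C(k) = h_k
    dh_out <- if (is.null(carry_out)) dFC[[k]] else {
      dlam[nL + 1L] <- dlam[nL + 1L] + sum(carry_out * fw$FC[[k]])
      dFC[[k]] + lam[nL + 1L] * carry_out
    }
    carry_out <- dh_out
    lb2 <- linear_bwd(dh_out, fw$spikes[[nS + 1L]][[k]], par$fc2$W)
    g$fc2$W <- g$fc2$W + lb2$dW
    g$fc2$b <- g$fc2$b + lb2$db
    dI <- lif_bwd(nS + 1L, k, lb2$dx)
    lb1 <- linear_bwd(dI, cache$flat[[k]], par$fc1$W)
    g$fc1$W <- g$fc1$W + lb1$dW
    g$fc1$b <- g$fc1$b + lb1$db

    # unflatten into the (pooled) output of the last stage
    last_o_dim <- dim(fw$spikes[[nS]][[k]])
    dfeed <- lb1$dx
    if (cfg$pool_after[nS]) {
      dim(dfeed) <- c(last_o_dim[1L], last_o_dim[2L] / 2L,
                      last_o_dim[3L] / 2L, N)
      d_next <- avgpool2_bwd(dfeed, last_o_dim)
    } else {
      dim(dfeed) <- last_o_dim
      d_next <- dfeed
    }

    for (s in rev(seq_len(nS))) {
      do_s <- d_next
      if (s == cfg$tap_stage && !is.null(dtap_extra[[k]])) {
        do_s <- do_s + dtap_extra[[k]]
      }
      dI <- lif_bwd(s, k, do_s)
      cb <- conv2d_bwd(dI, cache$conv_in[[k]][[s]], par$stages[[s]]$W)
      g$stages[[s]]$W <- g$stages[[s]]$W + cb$dW
      g$stages[[s]]$b <- g$stages[[s]]$b + cb$db
      if (s > 1L) {
        d_next <- if (cfg$pool_after[s - 1L]) {
          avgpool2_bwd(cb$dx, dim(fw$spikes[[s - 1L]][[k]]))
        } else cb$dx
      } else {
        dxg <- cb$dx
        n_idx <- fw$map_idx[k]
        if (n_idx >= 1L) {
          M <- fw$maps[[n_idx]]
          dX <- dxg * broadcast_gate(M, cfg$in_channels)
          dM_k <- channel_sum(dxg * cache$frames[[k]])
          dmaps_acc[[n_idx]] <- if (is.null(dmaps_acc[[n_idx]])) dM_k
                                else dmaps_acc[[n_idx]] + dM_k
        } else {
          dX <- dxg
        }
        if (need_dx) dX_steps[[k]] <- dX
      }
    }
  }

  # decay factors live behind a logistic squashing
  g$lif_rho <- dlam * lam * (1 - lam)
  if (!cfg$learnable) {
    g$lif_rho[] <- 0
    g$lif_vth[] <- 0
  }
  out <- list(grads = g)
  if (need_dx) {
    out$dX_steps <- dX_steps
    out$dX <- Reduce(`+`, dX_steps)
  }
  out
}

# Joint objective and its full gradient on one batch.
# frames: list of K (C, H, W, N) tensors; labels: integer vector in 1..n_class.
snn_loss_grad <- function(model, frames, labels, weights,
                          kernel = laplacian_kernel(), Te = 6,
                          spike_mode = "hard", need_dx = FALSE,
                          attack = FALSE) {
  cfg <- model$config
  fw <- snn_forward(model, frames, Te = Te, spike_mode = spike_mode,
                    keep_cache = TRUE)
  N <- fw$N
  sm <- softmax_cols(fw$Y)
  idx <- cbind(labels, seq_len(N))
  Lc <- -mean(log(pmax(sm[cbind(labels, seq_len(N))], 1e-300)))
  dY <- sm
  dY[idx] <- dY[idx] - 1
  dY <- dY / N
  if (attack) {
    # robustness is defined on predictions: attack the classification term
    bw <- snn_backward(model, fw, dY, dmaps = NULL, need_dx = TRUE)
    return(list(fw = fw, Lc = Lc, dX = bw$dX, dX_steps = bw$dX_steps))
  }
  alpha <- weights$alpha
  Lm <- 0
  dmaps <- NULL
  if (length(fw$maps) > 0L) {
    al <- attention_loss_batch(fw$maps, weights, kernel, gradient = TRUE)
    Lm <- al$value
    dmaps <- lapply(al$grads, function(dm) (1 - alpha) * dm)
  }
  bw <- snn_backward(model, fw, alpha * dY, dmaps = dmaps, need_dx = need_dx)
  list(fw = fw, Lc = Lc, Lm = Lm,
       loss = alpha * Lc + (1 - alpha) * Lm,
       terms = if (length(fw$maps) > 0L) al$terms else NULL,
       grads = bw$grads, dX = bw$dX, dX_steps = bw$dX_steps)
}

softmax_cols <- function(Y) {
  m <- apply(Y, 2L, max)
  e <- exp(sweep(Y, 2L, m))
  sweep(e, 2L, colSums(e), `/`)
}
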
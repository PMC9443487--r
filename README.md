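# spikegate

Spiking neural networks with learned top-down attention gating.

## The problem

Directly trained spiking neural networks (SNNs) — stacks of discrete-time
leaky integrate-and-fire (LIF) layers trained with surrogate-gradient
backpropagation through time — are attractive for event-driven hardware
because silent neurons cost nothing. But they spend spikes indiscriminately
across the whole visual field and are easy to fool with small adversarial
perturbations. `spikegate` implements and evaluates a closed-loop remedy:
a small *analog* generator network watches the SNN's own features and feeds
back a spatial **attention map** that multiplicatively gates the SNN's
input, so the network concentrates its spiking budget on the informative
part of the scene. The attention is learned **without any mask
annotations**, from a weakly supervised objective.

The package is for computational-neuroscience and neuromorphic-computing
researchers who want a fully inspectable, desk-scale implementation of this
model family — every forward step, gradient, attack, and operation count is
ordinary R (with compiled convolution kernels), with tests tying each piece
to independent oracles.

## The model

One LIF layer step, with per-layer learnable decay `λ` and threshold
`V_th` (hard reset, `H(0) = 1`):

    h_k = λ h_{k−1} (1 − o_{k−1}) + I_k,      o_k = H(h_k − V_th)

and the rectangular surrogate `∂o/∂h ≈ 1[|h − V_th| < a] / 2a` for
training. Every `T_f` the extractor's penultimate-stage spikes, averaged
over the window, pass through a 3-layer deconvolutional generator `A`, and

    M_n = sigmoid(T_e · LayerNorm(A(mean F)))

gates the input of the spike-encoding layer: `X(t) × M_n` (the initial map
is all-ones). Classification reads a learnable decoder over the
concatenated per-step classifier outputs. Everything is trained jointly on

    L = α L_C + (1 − α) L_M,
    L_M = (1/NP) Σ_n [ γ‖M_n‖₁ − β‖M_n − mean(M_n)‖₂² + (1−γ−β)‖M_n ∗ K‖₁ ]

with `α = 0.10, β = 0.40, γ = 0.51`, `K` a 4-neighbor Laplacian: sparse,
diverse (gates pushed to 0/1), smooth attention maps that must not hurt
accuracy. Robustness is measured under an L∞ projected-gradient-descent
attack (10 iterations, per-iteration projection) through the **complete**
unrolled closed loop, attention included; efficiency as firing rates and
event-driven multiply-accumulate counts.

## Worked example

```r
library(spikegate)

# 1500 labelled 16x16 scenes (disk vs cross on a dim textured background)
train <- gen_scene_dataset(1500, classes = 2, size = 16, seed = 0)
test  <- gen_scene_dataset(300,  classes = 2, size = 16, seed = 100)

cfg <- snn_config(in_size = 16L, x = 8L, K = 4L, n_class = 2L,
                  a = c(1.5, rep(0.5, 6)))   # wide encoder window
fit <- snn_train(
  snn_model(cfg, seed = 0),
  list(x = train$x, y = train$y),
  train_config(epochs = 15L, batch_size = 100L, lr = 0.01,
               warmup_epochs = 3L, attention_warmup = 3L,
               attention_warmup_acc = 0.9, seed = 0,
               target_accuracy = 0.97))
glance(fit)
#> # A tibble: 1 x 6
#>   epochs  loss accuracy params attention learnable
#>    <int> <dbl>    <dbl>  <int> <lgl>     <lgl>
#> 1     10 0.134    0.973  61948 TRUE      TRUE

mean(snn_predict(fit, test$x) == test$y)      # held-out accuracy
#> [1] 0.97

# where does the trained model attend?
tr <- snn_infer(fit$model, test$x[1, , , 1])
attention_gate_ratio(tr$maps[[1]], test$masks[, , 1])
#> [1] 5.171385

# efficiency and robustness
firing_rates(tr)$mean
#> [1] 0.1587419
robust_accuracy(fit$model, test$x[, , , 1:200, drop = FALSE],
                test$y[1:200], pgd_config(40/255, steps = 10L, seed = 0))
#> # A tibble: 1 x 4
#>   epsilon  seed     n accuracy
#>     <dbl> <int> <int>    <dbl>
#> 1   0.157     0   200     0.41
```

The gate ratio says object pixels receive ~5x the gate weight of
background pixels even though no mask was ever shown to the model; the mean
firing rate is the fraction of neurons spiking per layer-step; the robust
accuracy is held-out accuracy under the strongest tested attack budget
(40/255 — the matched attention-off baseline lands at 0.275 under the same
attack and seed in the acceptance study). Your exact values depend only on
the seeds you pass.

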
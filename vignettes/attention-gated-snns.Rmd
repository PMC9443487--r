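---
title: "Attention-gated spiking networks: model, objective, and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-gated spiking networks: model, objective, and evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`spikegate` simulates and trains a hybrid recognition model: a feedforward
convolutional **spiking** network does the sensory processing, while a small
**analog** network watches its features and feeds back a spatial attention
map that multiplicatively gates the spiking network's input. The closed loop
lets the model concentrate its limited spiking activity on the informative
part of the input, which is where its robustness and efficiency benefits
come from.

## Leaky integrate-and-fire dynamics

Every spiking layer consists of discrete-time leaky integrate-and-fire
units. With per-layer decay factor $\lambda \in (0,1)$, threshold $V_{th}$,
synaptic drive $I_k$ (a convolution or a dense product of the previous
layer's spikes), membrane potential $h$, and spikes $o$, one step is

$$h_{k} = \lambda\, h_{k-1} (1 - o_{k-1}) + I_{k}, \qquad
  o_{k} = H(h_{k} - V_{th}),$$

a *hard reset*: a unit that spiked has its residual potential wiped before
the next leak. Discretizing the continuous membrane equation with sampling
interval $T_d$ and time constant $\tau$ gives $\lambda = e^{-T_d/\tau}$;
the reset potential is 0 (the multiplicative reset form implies it), and
membrane resistance is absorbed into the synaptic weights. We adopt
$H(0)=1$ (a spike exactly at threshold) as a fixed, deterministic
convention; in floating point it is immaterial.

Both $\lambda$ and $V_{th}$ are **learnable per layer** (an ablation flag
freezes them). $\lambda$ is stored as an unconstrained scalar behind a
logistic squashing so it cannot leave $(0,1)$; $V_{th}$ is floored at
$10^{-3}$. Both initialize at 0.5 — $\lambda = 0.5$ corresponds to
$\tau = T_d / \ln 2$, a fast-leaking neuron appropriate for the short
($K \le 10$ step) inferences used here.

Training through the threshold uses a **rectangular surrogate gradient**:
the backward pass replaces $H'$ by $\frac{1}{2a}\,\mathbf{1}[|h - V_{th}| < a]$
with half-width $a = 0.5$ (configurable, per layer). The window integrates
to one and is centred on the threshold. The half-width may be set per
spiking layer, and the scaled-down study uses a *wider window at the
encoder* ($a = 1.5$) with $a = 0.5$ everywhere deeper. The reason is a
failure mode we observed with a uniform narrow window: encoder units over
a bright object are driven far above $V_{th} + a$, where the rectangular
window passes exactly zero gradient, so the classification loss loses its
grip on precisely the gates that matter and the sparsity term freely
suppresses the object — the learned attention then inverts (attends
background). Widening only the encoder window restores that gradient
without blurring credit assignment in the spike-driven deep layers, whose
drive spread is much smaller.

## Architecture

The feature extractor is VGG-like: `n_stages` (default 6) 3×3 convolution
stages with widths $x, x, 2x, 2x, 4x, 4x$ and 2×2 average pooling after
every second stage. Only the first (encoding) layer consumes real values;
every deeper layer consumes binary spikes. The classifier flattens the last
pooled stage into a spiking hidden layer (default 256 units) followed by a
readout layer.

The **readout is a non-spiking leaky integrator**: its membrane potential
(learnable decay, no threshold, no reset) is the per-step classifier output
$F_C(k)$. This is a deliberate design choice: we first implemented a
spiking readout and found that with a handful of output units the readout
falls silent within two epochs on small tasks — its per-step output becomes
a constant vector, the decoder loses all class information, and training
collapses to chance. A potential-accumulating readout is the standard
direct-training remedy and is what the package ships.

The final prediction is a **learnable decoder** over time:
$Y = W_C^\top [F_C(T_d)^\top, \dots, F_C(K T_d)^\top]^\top + b_C$, a strict
generalization of averaging the per-step outputs.

## Top-down attention

Every $T_f$ milliseconds (default $T_f = 2 T_d$) the spikes at the
extractor's *tap point* — the penultimate convolution stage — are averaged
over the window and passed to a 3-layer deconvolutional generator with
ReLU between layers and channel widths $c \to c/2 \to c/4 \to 1$. Because
the tap sits after two pooling stages, two of the layers are kernel-4,
stride-2 transposed convolutions (each an exact spatial doubling at
padding 1) and the remainder are stride-1 3×3 convolutions; the output is a
single-channel map at input resolution. The raw map is standardized over
its elements (layer normalization with $\epsilon = 10^{-5}$ and *no*
learned affine terms — nothing in the formulation calls for them and they
would fight the temperature) and squashed:

$$M_n = \sigma\!\left(T_e \cdot \mathrm{LayerNorm}(A(\bar F_n))\right).$$

Gates therefore lie strictly in $(0,1)$ and the map is invariant to affine
rescaling of the generator output. The **temperature** $T_e$ controls gate
hardness: it anneals linearly from 1 to its maximum (default 6) over the
first 80% of training epochs and stays at the maximum at inference. Starting
soft keeps the sigmoid's gradient alive early; ending hard gives nearly
binary gates.

The map multiplies the input elementwise (broadcast across channels). The
initial map $M_0$ is all-ones — no preference. The cadence is:

* **static inputs** (one frame replicated over $K$ steps): steps in the
  first window use $M_0$; one map is generated from the first window's
  features and shared by all later steps (`[0,0,1,1,1,1]` for $K=6$).
* **dynamic inputs** ($K$ accumulated event frames): the map regenerates
  every window; steps of window $n+1$ use $M_n$
  (`[0,0,1,1,2,2,3,3,4,4]` for $K=10$).

The number of generated maps per inference is
$N = \lfloor K T_d / T_f \rfloor$. In static mode only one *distinct* map
exists; averaging the per-map loss over $N$ identical copies equals the
single-map value, so the implementation scores the distinct map once. In
dynamic mode a map is generated at the end of every complete window; the
last one is consumed only by the attention loss.

# The objective

Classification and attention are trained jointly:

$$\mathcal{L} = \alpha \mathcal{L}_C + (1-\alpha)\mathcal{L}_M,$$

with $\mathcal{L}_C$ the softmax cross-entropy on the decoded $Y$ only.
$\mathcal{L}_M$ is weakly supervised — no mask annotations anywhere — and
averages three terms over the $N$ maps and $P$ gates per map:

$$\mathcal{L}_M = \frac{1}{NP}\sum_{n=1}^{N}\Big[
 \gamma\|M_n\|_1 \;-\; \beta\|M_n - \mathrm{mean}(M_n)\|_2^2
 \;+\; (1-\gamma-\beta)\,\|M_n * \mathcal{K}\|_1\Big].$$

The L1 term pulls maps toward sparsity, the negated variance term pushes
gates toward the extremes 0/1 (away from a useless uniform 0.5), and the
high-pass term makes the attended region spatially coherent.
$\mathcal{K}$ defaults to the 4-neighbor Laplacian
`[[0,1,0],[1,-4,1],[0,1,0]]`. The correlation uses **mirror boundary
padding** (reflect about the edge pixel). Mirror padding passes no
constant signal, so the degenerate cases stay analytic (all-ones map costs
exactly $\gamma$; all-zeros costs 0). We first used replicate padding,
which also kills constants, and found a failure mode: replicate padding
prices a gate transition along the image border at roughly half an
interior transition, and the generator can produce border-localized
patterns almost for free through its own padding artifacts — trained maps
collapsed to an input-independent frame of high gates hugging the border.
Mirror padding removes the discount and the artifact with it. The weights are
$\alpha = 0.10$, $\beta = 0.40$, $\gamma = 0.51$ (so the smoothness weight
is $0.09$); the loss consumes map values *after* the sigmoid, since those
are what gate the encoder.

# Training

The unrolled $K$-step graph — gating, extractor, classifier, decoder, and
generator — is differentiated end to end with no detaching at the map
boundary; a map's gradient flows back through the generator into the tap
features of the window that produced it. The optimizer is mini-batch SGD
with momentum 0.9, Kaiming-uniform initialization, and a linear
learning-rate warm-up from 10% of the base rate over the first 5 epochs
(no decay afterwards by default; a cosine option exists).

Three stability choices deserve explanation:

* **Gradient clipping** (global norm, default 1.0). Surrogate-gradient
  backpropagation through the unrolled graph occasionally produces batch
  gradients whose norm rivals the weight norm itself; a single unclipped
  momentum step then knocks the network into a dead symmetric state
  (constant outputs, chance accuracy) from which the surrogate gradient
  cannot recover. We observed exactly this collapse at every unclipped
  learning rate above ~$10^{-3}$; clipping at unit norm makes the
  configured rates stable without changing gradient directions.
* **Attention burn-in** (`attention_warmup` / `attention_warmup_acc`; at
  least 3 epochs and training accuracy 0.9 in the study). The closed loop
  switches on only after the feedforward path actually works; together with
  the generator's zero-initialized output layer (untrained maps are exactly
  uniform), this means the map's spatial orientation is decided by
  classification gradients on meaningful features. Switching uniform maps
  onto a working classifier makes the classification loss re-activate
  exactly on the gates whose suppression would hurt it, which anchors the
  attended region to the object. Without the burn-in we found the sparsity
  objective, acting on a random network, settles maps into arbitrary
  input-independent patterns — sometimes even anti-object ones.
* **Smooth verification mode.** With hard spikes the forward map is
  piecewise constant, so finite differences cannot probe the surrogate
  backward pass. For gradient verification the package provides a forward
  mode whose spike function is the hard sigmoid
  $\mathrm{clip}((h - V_{th})/2a + 1/2,\,0,\,1)$ — its exact derivative is
  the rectangular surrogate window. The backward code is *identical* in
  both modes, so a finite-difference match in smooth mode (the test suite
  checks $10^{-5}$ relative) verifies the very gradients used in hard-mode
  training.

Divergence (non-finite loss) aborts with a diagnostic rather than
continuing silently.

# Adversarial evaluation

Robustness is measured as accuracy under an $L_\infty$ projected gradient
descent attack: $X_0 = X + \mathrm{Uniform}(-\epsilon, \epsilon)$, then ten
iterations of $X_{i+1} = \Pi[X_i + \eta\, \mathrm{sgn}(\nabla_X
\mathcal{L}_C)]$. $\Pi$ projects onto the intersection of the
$\epsilon$-ball around the clean input and the valid intensity range after
*every* iteration — without the per-iteration ball projection the stated
budget could silently be exceeded. The gradient runs through the complete
unrolled graph, attention loop included (a flag can freeze the maps to
demonstrate that this path matters). The attacked loss is the
classification term only, since robustness is defined on predictions. For
event data the real-valued perturbation is added directly to the
accumulated frame tensors, never re-binarized. For the synthetic study the
step size is $\eta = \epsilon/4$.

# Efficiency profiling

*Firing rates* are spiking proportions per layer and step; the mean rate is
total spikes over total neurons times steps. *Operation counts* are
event-driven on the spiking path: a silent neuron triggers no post-synaptic
work, and each spike contributes its downstream kernel support — truncated
at borders — times the downstream channel count. Where average pooling sits
between stages, the downstream multiplication happens once per pooled
value, so the count is driven by *active pooled sites* (any spike in the
2×2 block); at full spike density the estimate collapses exactly to the
dense convolution count. The encoder convolution on real inputs, the
generator (once per generated map) and the decoder are counted densely;
an optional `skip-zero` mode scales the encoder count by the nonzero
fraction of the gated input, the most optimistic reading of gated
hardware. Accumulate-only spike operations are reported in the same MAC
unit, with the spiking subtotal kept separate so it can be read as ACs.
Dense counts use border-truncated kernel support too, so the two accounting
sides are consistent.

# Synthetic study data

No external dataset defines the package's tests. The generators emulate:

* **Static scenes** (`gen_static_scene`): a 16×16 textured background
  (smoothed uniform noise, intensities 0.05–0.35) with one bright
  (≈0.75–0.9) class-determined shape — disk, cross, or bar — at a random
  pose, plus mild sensor noise. The ground-truth mask covers 10–25% of the
  pixels and the object/background mean-intensity margin is at least 0.3.
  Masks are *never* shown to the model; they only score the learned
  attention afterwards.
* **Perturbations**: integer translation and nearest-neighbor rotation
  transform image and mask together; additive Gaussian noise perturbs only
  the image.
* **Event streams** (`gen_moving_events`): a shape translating along a
  seeded straight path emits ON events at its leading edge and OFF events
  at its trailing edge, Bernoulli-thinned, with microsecond timestamps;
  frames accumulate in half-open 5 ms bins over 10 steps, clipped to
  binary before the encoder (raw counts are available; the attack always
  receives the real-valued tensors). A reader/writer pair for the 5-byte
  address-event binary dialect (x, y, polarity bit, 23-bit microsecond
  timestamp) connects to real recordings.

What the generators do **not** emulate: natural image statistics (color,
clutter, occlusion), class-dependent background correlations, sensor noise
models, or multi-object scenes. Passing the package's tests therefore shows
that the mechanism works — maps localize objects, firing drops, robustness
improves — not that those effects transfer at full scale to natural-image
benchmarks, which require orders of magnitude more capacity and data.

# Study conditions and problem sizes

The scaled-down experiment the tests and the acceptance script run: a
VGG-8c backbone on 16×16 grayscale scenes, two shape classes, $K = 4$
steps, $T_f = 2T_d$, 1500 training and 300 held-out scenes, batch 100,
learning rate 0.01 (3 warm-up epochs), momentum 0.9, clip norm 1.0,
attention burn-in (3 epochs minimum, accuracy trigger 0.9), surrogate
half-widths $(1.5, 0.5, \dots)$
(encoder wide, deep layers narrow), at most 15 epochs with early stop once
training accuracy reaches 97%, seeds {0, 1, 2}; PGD with budgets
{10, 20, 40}/255, $\eta = \epsilon/4$, 10 iterations on 200 held-out
scenes. The batch size and learning rate differ
from the full-scale defaults (200 / 0.1) because the toy model's loss
surface tolerates proportionally smaller steps; both are recorded in
`train_config()` and the choice is documented here once. Everything is
seeded: weights and data by the run seed, shuffling by the training seed,
attack initialization by the attack seed.

# Known limitations

* Stride-1 3×3 convolutions and 2×2 average pooling only; no batch norm or
  residual paths (deliberately out of scope).
* Attention gates the encoder only; gating middle layers is an open
  extension.
* The trainer targets desk-scale problems; it is single-threaded,
  dense-tensor R/C++ and does not attempt GPU-scale reproduction of
  natural-image benchmarks.
* `num_maps()` counts complete windows; a trailing partial window
  contributes no map.
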
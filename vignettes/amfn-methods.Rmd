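---
title: "Adaptive multimodal fusion for clinical time series: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive multimodal fusion for clinical time series: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amfn)
```

## The problem

ICU-style monitoring produces several *modalities* per patient — ECG-derived
channels, blood pressures, respiration, intermittent labs — each with its own
channels, sampling pattern and gaps. The goal is a single predictive
representation per time window that (i) lets modalities inform each other,
(ii) down-weights uninformative or corrupted sources, and (iii) survives
partially missing modalities. `amfn` implements an adaptive multimodal fusion
network for this setting, together with the preprocessing pipeline and a
synthetic generator with known ground truth, so the whole stack is testable
without access-controlled clinical data.

## Model

Let $X^{(m)}$ be modality $m$'s imputed, z-scored window (channels
$\times$ 256) and $M$ the number of modalities.

**Encoders.** Each modality has its own encoder
$h^{(m)} = \phi_m(X^{(m)}) \in \mathbb{R}^d$ (default $d = 128$). The default
$\phi_m$ is a two-layer temporal convolution (kernel 5, stride 2, ReLU),
global average pooling over time, dropout, and a linear projection; a GRU
encoder is available behind `encoder_type = "gru"`, and a channel-mean +
linear encoder implements the "no feature extraction" ablation. Absent
modalities encode to the zero vector and carry a presence flag that excludes
them from every softmax below.

**Embedding standardization.** Embeddings are standardized per dimension,
$\tilde h^{(m)} = (h^{(m)} - \mu_m)/\sigma_m$, with $\mu_m, \sigma_m$ fitted
on training-set embeddings and then frozen (they are constants to the
optimizer, not batch statistics). We fit them once, from the initial encoder
state, before the first epoch: refitting every epoch rescales the inputs of
all downstream layers each time and measurably stalls convergence.

**Cross-modal attention.** Bilinear scores between standardized embeddings,
$\alpha_{ij} = \mathrm{softmax}_j(\tilde h^{(i)\top} W_a \tilde h^{(j)})$,
give attended embeddings $\hat h^{(i)} = \sum_j \alpha_{ij} \tilde h^{(j)}$.
The softmax runs over present modalities only and includes the self term.
Four heads are used by default, each with its own $W_a$; head outputs are
concatenated and linearly projected back to $d$. With one head the operation
is exactly the single-$W_a$ bilinear-softmax form.

**Modality graph and GCN.** A per-sample graph over modalities has edge
weights from cosine similarity $S(\tilde h^{(i)}, \tilde h^{(j)})$,
row-normalized to an adjacency $A_{ij} = S_{ij} / \sum_k S_{ik}$. The ratio
normalization is ill-defined when similarities change sign, so similarities
are clamped below at $10^{-8}$ first; a masked softmax over raw similarities
is available via `adjacency = "softmax"`. Two graph-convolution layers with
residual connections refine the attended embeddings,
$H^{(l+1)} = \mathrm{ReLU}(A H^{(l)} W^{(l)}) + H^{(l)}$ with
$H^{(0)} = \hat h$, and the rows of $H^{(L)}$ are concatenated into the
graph-level vector $Z \in \mathbb{R}^{Md}$. The graph is rebuilt per sample
from that sample's embeddings; it is not shared across a batch. Where the
narrative allows either choice, $A$ is built from the standardized
embeddings while the GCN input is the attended
embeddings.

**Gating and context-aware fusion.** Each modality gets a scalar gate
$\gamma_m = \sigma(w_m^\top g^{(m)}) \in (0,1)$ scaling its embedding
(absent modalities are gated to 0), where $g^{(m)}$ is the standardized
encoder embedding $\tilde h^{(m)}$ in the default wiring (below). A learned
query $q \in \mathbb{R}^d$ produces fusion weights
$\beta_m = \mathrm{softmax}_m(q^\top \gamma_m g^{(m)})$ and the fused
vector $F = \sum_m \beta_m \gamma_m g^{(m)}$, which lies in the convex
hull of the gated embeddings.

**Pipeline wiring and prediction head.** The fusion network (attention +
graph refinement, producing $Z$) and the dynamic weighting strategy
(gating + query fusion, producing $F$) are two mechanisms of one pipeline,
but how their outputs combine into the predictor is a genuinely open design
choice. We evaluated two candidates on synthetic tasks with a known
informative modality:

* *Parallel branches* (default: `dcmls_stage = "encoder"`,
  `head_input = "concat"`): gating/fusion read the standardized encoder
  embeddings and a linear head reads $\mathrm{concat}(Z, F)$. Both branches
  train; prediction quality is carried mostly by $Z$. A caveat we observed
  and document honestly: because $Z$ alone suffices for prediction, the
  optimizer is free to silence the $F$ branch, and in some seeds it does —
  either by collapsing the gates or by routing $\beta$ onto gated-to-zero
  modalities. When that happens the gate/fusion weights stop being
  interpretable as modality-relevance scores (see Limitations).
* *Sequential* (`dcmls_stage = "gcn"`, `head_input = "F"`): gating/fusion
  read the GCN-refined embeddings and $F$ alone feeds the head. This looks
  attractive in principle (every mechanism sits on the gradient path), but in
  our experiments the d-dimensional bottleneck of products of saturating
  factors never learned the synthetic task at any alignment weight
  (test $R^2 \approx 0$ across seeds, with gates saturating at 0 or locking
  onto a noise modality), so it is available but not the default.

The training objective is
$L = L_{task} + \lambda_{rec} L_{rec} + \lambda_{align} L_{align}$:

* $L_{task}$ — MSE for regression; cross-entropy or focal loss (focusing
  parameter $\gamma_f$, reducing to cross-entropy at $\gamma_f = 0$) for
  binary outcomes.
* $L_{rec}$ — per-modality linear decoders reconstruct the imputed input
  window from $\tilde h^{(m)}$; the squared error is averaged over
  *originally observed* cells only, so imputed values are never targets.
* $L_{align}$ — for every unordered pair of co-present modalities,
  $\|u^{(i)} - u^{(j)}\|^2$ on L2-normalized embeddings $u$, which equals
  $2 - 2\cos(h^{(i)}, h^{(j)})$; a raw-scale variant is available. The pair
  set defaults to all co-present pairs within a window because no pairing
  algorithm is prescribed for this data type.

$\lambda_{rec} = \lambda_{align} = 0.1$ by default; no reference values
exist for these weights, so they are exposed in the configuration and the
ablation grid.

## Optimization

Adam (learning rate $10^{-3}$, cosine-annealed over the epoch budget), batch
size 256, weight decay $10^{-5}$, global gradient-norm clipping at 1.0,
dropout 0.5 in the encoders, Xavier initialization for fully connected and
Kaiming for convolutional weights, early stopping on validation loss with
patience 10 (ties keep the earliest best epoch, whose checkpoint is
restored). Training is deterministic given the seed: initialization,
shuffling and dropout all draw from seeded streams.

The network and its hand-derived backpropagation are implemented in R
matrix operations, with the convolution encoder and the masked
reconstruction loss in RcppArmadillo where the dense inner loops live. Two
numerical choices matter:

* **Stop-gradient through the adjacency.** $A$ is a function of the
  embeddings, but gradients are not propagated through the cosine
  similarities; $A$ is treated as a constant during backpropagation, as is
  common for dynamically built graph structure. Every other gradient path
  matches finite differences to ~1e-9 (the test suite checks this), so the
  only bias in the gradient is this deliberate one.
* **Frozen standardization statistics** (above).

Degenerate inputs are handled explicitly: constant channels z-score to zero
with a flag, zero-norm embeddings fall back to the similarity clamp with a
warning, fully absent modalities are masked out of every softmax, and a
non-finite loss aborts training naming the offending component.

## Preprocessing

The pipeline order is fixed — align, segment, filter, impute, z-score — and
all statistics are fitted on training patients only:

1. **Align/resample**: linear interpolation onto a unit grid, bridging only
   neighbour pairs at most `max_gap` (default 10) steps apart; wider gaps
   stay missing for the imputation stage to handle, because linear
   interpolation across long gaps fabricates trends.
2. **Segment**: half-open, 0-based windows of 256 steps, stride 128;
   incomplete tails dropped.
3. **Filter**: a window is dropped iff its pooled missing fraction across
   all modalities, channels and steps exceeds 0.40 strictly ("more than
   40%" read literally; a window at exactly 40% is retained). Cells are
   pooled unweighted.
4. **Impute**: forward-fill gaps up to `long_gap` steps (default 60; a
   "long gap" has no canonical length, so the boundary is exposed in the
   configuration); longer gaps and leading gaps take the channel's
   training mean.
5. **Z-score** per modality channel with training statistics; degenerate
   channels (sd < 1e-8) divide by 1 and are flagged.

A modality entirely absent from a window keeps `modality_present = 0` and is
filled with the training mean (zero after z-scoring), so the encoders see
finite inputs and the masking contract does the rest. The physical step
length (1 s vs 1 min) is metadata: the model sees step indices.

## Synthetic generator

The generator emulates the structure of multi-hour multimodal ICU records
while staying fully controlled: per patient and modality a latent AR(1)
trajectory (autocorrelation 0.9, unit marginal variance, `latent_dim` 4)
drives the observed channels through a fixed random loading matrix plus
Gaussian noise (sd 0.5). Contiguous drop-out gaps with geometric lengths
(mean 10 steps) are carved out at a 10% target rate per modality — matching
roughly 85–92% coverage reported for public ICU cohorts — and all channels
of a modality share the mask, mimicking sensor drop-out. Defaults: 3
modalities, 2 channels each, 512-step records.

The continuous outcome is a linear function of the time-averaged latents of
the *informative* modalities plus, for each planted interaction pair, a
linear function of the time-averaged elementwise latent products; the score
is standardized across patients before adding label noise (sd 0.1), so the
noise level is relative and the task loss is commensurate with the auxiliary
losses. Binary labels threshold the score at its median, giving balanced
classes. The ground truth (latents, loadings, effective coefficients, masks)
is returned, so tests can verify recovery exactly.

What the generator does *not* emulate: waveform morphology (no QRS
complexes, no pulse pressure shapes), cross-modality missingness
correlation, non-stationarity, or label shift. Passing tests therefore
demonstrate that the mechanisms work as specified on structured synthetic
signals — not clinical performance.

## Other design choices that were genuinely open

* Missing-threshold boundary: strict inequality (drop only above 40%).
* Window coordinates 0-based and half-open.
* $\psi_m$ (the gating branch encoder) shares weights with $\phi_m$; a
  separate-encoder option would double parameters for no tested benefit.
* The normalized and the gated embedding get distinct names (`h_norm`,
  `h_gated`) rather than sharing one symbol.
* Generic joint-encoder composition: the "unified multimodal
  representation" is realized as the composition of
  standardization–attention–graph–gating–fusion; there is no separate
  monolithic encoder.
* GCN residuals on by default (`residual = FALSE` restores the bare
  propagation rule).
* The GroundTruth JSON sidecar stores coefficients, loadings, realized
  missingness and scores; full latent trajectories stay in memory (they are
  large and reproducible from the seed).
* Classification threshold 0.5; early-stopping ties keep the earliest
  epoch; five-fold cross-validation loops over patient folds.
* Mixed precision and multi-device training are out of scope at this scale.

## Problem sizes used by the checks

The packaged experiments run at a desk scale chosen so the full suite
completes on one CPU: recovery and ablation experiments use 2,000 synthetic
patients, 512-step records (three 256-step windows per patient), embedding
dimension 16 and 30-epoch budgets over 5 training seeds on fixed cohorts
(run-to-run randomness covers initialization, shuffling and dropout); the
acceptance script uses the same conditions. Property checks (simplex constraints, oracle
equivalence) run on thousands of small random instances. These sizes are
statements about the test design, not about the model's capacity.

## Known limitations

* The gradient bias from the adjacency stop-gradient means the similarity
  graph adapts only through the embeddings, not through an explicit
  structure objective.
* Window-level labels inherit the patient label; a window covering half a
  record can explain only part of the label variance by construction, so
  absolute $R^2$ on the synthetic task is bounded well below 1.
* Selector redundancy: the gate $\gamma$ and the fusion weight $\beta$ are
  two multiplicative selectors over the same modalities, and the
  graph-level representation $Z$ carries the predictive signal on its own.
  On synthetic recovery tasks the trained model reliably identifies the
  informative modality with *one* of the two selectors, but which one
  survives training is seed-dependent; joint $\gamma$-and-$\beta$ recovery
  should not be relied on. The same redundancy (the no-attention variant
  still mixes modalities through the GCN) keeps the measured ablation
  margins small relative to run-to-run noise at desk scale.
* The R + RcppArmadillo implementation is fast enough for the packaged
  scales but is not a GPU training stack; at hundreds of thousands of
  windows a different backend would be the right tool.
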
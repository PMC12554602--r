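---
title: "OncoFusion: models, design choices and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{OncoFusion: models, design choices and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models it
implements, the assumptions behind them, the parameters that matter, the
places where the design was genuinely open and how we resolved them, and
what the test suite does and does not demonstrate.

## 1. The model

Each patient is a triple of modalities — an image array
$X \in \mathbb{R}^{H \times W \times C}$, a genomic token sequence
$g \in \{0, \dots, V-1\}^m$, and a clinical vector
$c \in \mathbb{R}^p$ — with a class label $y \in \{0, \dots, K-1\}$, a
domain tag (source/target) and a modality-presence mask.

**Encoders.** Three modality-specific encoders map into a shared latent
space $\mathbb{R}^d$. The image encoder is a stack of strided valid
convolutions with ReLU, global average pooling over the final feature
map, and a linear projection to $d$. The genomic encoder embeds tokens,
adds fixed sinusoidal positional encodings, applies `nLayers` blocks of
multi-head scaled dot-product self-attention
$\mathrm{softmax}(QK^\top/\sqrt{d_k})V$ with residual connections, mean-
pools over tokens and projects to $d$. The clinical encoder is an MLP
with ReLU and dropout. All three are written directly in R, with
hand-derived backpropagation; the gradient of the full composite loss
was verified against central finite differences during development, and
the attention forward pass is tested against an independent nested-loop
oracle.

**Fusion and classification.** Present-modality embeddings are scored by
a learned vector $w$ ($e_i = w^\top Z_i$), normalized by a softmax over
the *present* modalities only, and combined convexly,
$Z_{fused} = \sum_i \alpha_i Z_i$. Absent modalities receive weight
exactly 0 — they are excluded from the softmax rather than imputed. A
linear softmax head produces class probabilities. The training objective
is cross-entropy plus the structured penalty
$\lambda\|w\|^2 + \beta\|W_{out}\|_F^2$ (an undifferentiated global
weight decay over all parameters is available via
`trainConfig(weightDecay=)` as the coarser alternative), plus weighted
auxiliary terms described below.

**Cross-modal alignment.** The triplet loss
$\max(0, \tau + \|Z_a - Z^+\|^2 - \|Z_a - Z^-\|^2)$ pulls an anchor
embedding towards the same patient's embedding from another modality and
away from an embedding of a different-class patient. We deliberately use
this standard ordering — anchor close to positive — because the
alternative sign convention (which rewards anchor–positive distance)
contradicts the stated purpose of keeping semantically similar cases
nearby; `contrastiveAlignmentLoss(..., literal = TRUE)` exposes the
swapped form for inspection but it is never used in training. Triplets
are formed per batch: one anchor per sample with at least two present
modalities, the negative drawn from the batch members of a different
class.

**Adversarial domain adaptation.** A 2-layer MLP discriminator
$D(\cdot)$ on the fused embedding plays the minimax game
$L_{DA} = \mathbb{E}_s \log D(Z) + \mathbb{E}_t \log(1 - D(Z))$: $D$
ascends, the encoders descend, in alternating updates (a
gradient-reversal-style joint mode is available via
`trainConfig(daMode = "grl")`). Two stability parameters matter. With a
single discriminator step per batch, the encoder's best response to a
*stale* discriminator is to swap the two domains across the decision
boundary rather than merge them — the adversarial loss then falls well
below $2\log\tfrac12$ while the domains stay separated. Keeping the
discriminator near-optimal removes that degenerate response, so the
default gives it `daDiscSteps = 3` updates per encoder update at
`daDiscLrMult = 5` times the encoder learning rate. With these defaults
the logged adversarial loss hovers near $2\log\tfrac12 \approx -1.386$
(a confused discriminator), which is the intended equilibrium.

**Consistency.** An optional penalty
$\mathbb{E}\|f(x_s) - f(x_t)\|^2$ on paired source/target predictions.
No pairing is intrinsic to unpaired cohorts, so pairing is defined
within each batch by matching class labels (seeded random matching among
same-label source/target members); this is an artifact-level decision,
off by default (`consistencyWeight = 0`).

**Uncertainty.** `mcDropoutPredict()` keeps every dropout site live for
$T$ forward passes; the mean of the $T$ probability vectors approximates
the posterior predictive, the per-class empirical variance measures
epistemic uncertainty, and the Shannon entropy of the mean summarizes
it. Per-modality variances $\sigma_i^2$ are obtained by re-running the
probe with all *other* modalities masked — the unimodal perturbation
isolates one stream's reliability — and averaged over classes (an
ensemble of independently seeded models would be the alternative
protocol; the MC probe is the default because it needs one model).
Inverse-variance weights $w_i \propto 1/\sigma_i^2$ define an
alternative, uncertainty-driven fusion. How the two weighting schemes
should interact is genuinely open; `predictWithStrategy()` therefore
exposes `attention` (the trained pathway, the default), `inverse_variance`,
and `product` ($\alpha_i w_i$ renormalized) rather than hard-wiring one.

**Calibration.** $L_{cal} = |H(\hat y) - A(\alpha)|$ couples prediction
entropy to attention entropy. $H(\hat y)$ lives in $[0, \log K]$ but
$A(\alpha)$ in $[0, \log M]$ with $M \le 3$ present modalities, so the
raw difference is scale-inconsistent whenever $K \ne M$; the default
normalizes each entropy by its own maximum, bounding the loss in
$[0, 1]$ (raw mode: `normalized = FALSE`). Exact zeros in $\alpha$ are
treated as absent modalities and excluded from the attention entropy's
support. Whether this term belongs in the training objective or only in
diagnostics is not settled; it is trained with a small default weight
(0.1) and can be disabled.

**Treatment policy.** Patient trajectories are modeled as a tabular MDP
$(S, A, P, r, \gamma)$. `trainQLearning()` runs ε-greedy episodes with
uniform experience replay, a hard-copied target network and gradient
descent on
$\mathbb{E}[(Q(s,a) - (r + \gamma \max_{a'} Q_{tgt}(s',a')))^2]
- \lambda_H H(\pi)$, where the policy for the entropy bonus is
$\pi = \mathrm{softmax}(Q(s,\cdot)/\text{temperature})$ — Q-learning has
no explicit stochastic policy, and the softmax reading at temperature 1
is the standard way to give the entropy term meaning. Distributional
value learning is mentioned in this literature without an algorithmic
specification; it is *not* implemented (no quantile or categorical
parameterization is guessed). `valueIteration()` is the in-package
oracle: synchronous sweeps to a sup-norm tolerance, terminal states
pinned to value 0. `toyOncologyMdp()` ships a fixed 6-state / 3-action
treatment process (remission, stable, two progression stages, toxicity,
absorbing terminal) whose rewards favor response and penalize
toxicity-driven complications; its tables are constants, so the `seed`
argument is accepted only for interface symmetry.

## 2. Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `d` | 32 | shared latent dimension; desk-scale |
| `d_k`, heads, layers | 8, 2, 2 | genomic attention geometry; desk-scale |
| `dropout` | 0.1 | dropout rate at the MC-dropout sites (clinical hidden layers and every modality embedding), dimensionless |
| `lr` | 2e-4 | initial Adam rate; the convention for this architecture family at scale, with $\beta_1 = 0.9$, $\beta_2 = 0.999$, cosine annealing, batch 64 |
| `lambda`, `beta` | 1e-4 | structured L2 penalties on $w$ and $W_{out}$ |
| aux weights | 0.1 each | contrastive and calibration terms; no principled value exists, so they are exposed and documented |
| `daWeight` | 0 (off) | adversarial term weight; 0.3 in the packaged study conditions |
| `modalityDropoutRate` | 0 (off) | training-time whole-modality masking |
| `epsilon` schedule | 1 → 0.05 over 2000 steps | exploration for Q-learning |
| `temperature` | 1 | softmax policy temperature for the entropy term |
| EMA decay | 0.99 | weight averaging in `runTraining` (epoch granularity) |

Desk-scale runs — everything in the tests and the acceptance script —
use `lr = 0.01`, batch 32 and 6–10 epochs: cohorts of a few hundred
patients with $d = 32$ need a larger step than GPU-scale corpora, and
these sizes keep a full training run in the tens of seconds on one CPU.
These are the package's stated problem sizes for its own evidence.

## 3. The synthetic cohort generator

`generateCohort()` draws one latent prototype per class
(dimension 8) and renders it per modality: the image is the prototype
expanded over a fixed low-frequency 2-d cosine basis; the genomic
sequence is sampled from a class-conditional categorical whose logits
are a fixed linear map of the prototype, scaled by the genomic
informativeness weight (weight 0 ⇒ uniform tokens — the discrete
modality's noise is its sampling, so `noiseSd` does not apply to it);
the clinical vector is a fixed affine map of the prototype. Continuous
modalities get additive $\mathcal N(0, \text{noiseSd}^2)$ noise scaled
against an informativeness weight in $[0,1]$. Labels are uniform over
$K$. After a seeded shuffle, the first
$\lfloor \text{targetFraction} \cdot n \rfloor$ patients become the
target domain and their image and clinical features are transformed
$x \mapsto \text{scaleShift}\cdot x + \text{meanShift}$ — an
acquisition-style covariate shift; token identities are never shifted,
because platform shift should not rewrite biology. Missingness masks
each modality independently at `missingRate`, restoring one uniformly
chosen modality when all three would drop; absent content is a zero
sentinel behind a `FALSE` mask and must never be read.

What this emulates: multimodal class structure with controllable
per-modality signal, covariate shift between two domains, and random
modality availability. What it does not emulate: real histology texture
or genomic linkage structure, label noise, class imbalance, per-patient
heteroscedastic reliability, survival endpoints, or the statistics of
any real cohort. Passing tests therefore demonstrate that the
*mechanisms* behave as designed under known ground truth — attention
finds the informative stream, adversarial alignment reduces a real
divergence, modality dropout buys robustness — not that any particular
accuracy would transfer to clinical data.

## 4. Numerical choices

* Cross-entropy probabilities are clipped at $10^{-12}$; discriminator
  sigmoids at $10^{-7}$ (with a warning in the exported loss).
* Softmaxes subtract the row maximum before exponentiation.
* $0 \log 0 = 0$ throughout; natural logarithms everywhere; normalized
  entropies divide by $\log(\text{length})$, with length-1 vectors given
  entropy 0.
* Glorot-style $\mathcal N(0, 2/(n_{in}+n_{out}))$ initialization,
  zero biases; all seeds below $2^{31}$, with child seeds derived by a
  fixed affine-mod rule so that one user seed covers initialization,
  shuffling, dropout and modality dropout.
* Argmax ties (predictions, greedy actions) break towards the lowest
  index, documented and tested.
* Inverse-variance weights: $+\infty$ variance ⇒ weight 0; all finite
  variances numerically zero ⇒ equal weights over the finite entries;
  a strict subset of zeros ⇒ the weight splits equally among the zeros
  (the limit of the formula).
* MMD uses the biased estimator with a Gaussian kernel; the default
  bandwidth is the median heuristic over pooled pairwise distances,
  which makes the value invariant to a global rescaling of the
  embeddings — the property that makes paired comparisons across
  separately trained models fair.
* Value iteration stops when the sup-norm sweep change is below
  `tolerance` (default 1e-8); checkpoints and MDPs are written as JSON
  with 17 significant digits, enough for bit-exact double round trips.
* EMA tracking in `runTraining` operates at epoch granularity (the
  optimizer state is rebuilt between epochs); per-step EMA would need an
  optimizer callback and is out of scope.

## 5. Study conditions behind the packaged checks

The training-based checks in `test-acceptance.R` fix their conditions
once:

* *Informative-modality recovery*: $n = 500$, $K = 2$, informativeness
  $(0, 0, 1)$, noise 1, seeds 1–3; the mean attention weight on the
  clinical stream must exceed both others in at least 2 of 3 seeds.
* *Domain-adaptation effect*: $n = 240$, informativeness
  $(0.4, 0.4, 0.6)$, noise 1.2, mean shift 2 on half the cohort;
  adversarial weight 0.3 against a weight-0 baseline, same seeds; MMD of
  fused source vs target embeddings (median-heuristic bandwidth per
  model) must drop in at least 2 of 3 seeds.
* *Modality-dropout robustness*: $n = 240$, equal informativeness 0.7;
  the accuracy drop, averaged over removing each modality at test time
  and over 3 seeds, must be smaller for the model trained with
  modality dropout 0.3 than for its identically configured counterpart.
* *Fusion ablation ordering*: $n = 400$, informativeness $(0, 0, 1)$,
  noise 1.5, **35% modality missingness**, 3 seeds; attention fusion
  must match or beat uniform-mean fusion on mean accuracy. The
  missingness is the point: with all modalities always present, the
  encoders can emulate any fixed weighting by rescaling their outputs
  and the two fusion rules tie; when the present set varies per patient,
  uniform weights rescale the informative embedding patient by patient
  while attention does not — that is precisely the clinical regime the
  adaptive mechanism exists for.
* *Q-learning vs value iteration*: the shipped deterministic 4-state /
  2-action chain (`inst/extdata/chain_mdp.json`, $\gamma = 0.9$), 2000
  episodes, $\lambda_H = 0$; learned Q within sup-norm 0.05 of the
  oracle. On a deterministic MDP the TD targets are noiseless, so the
  learner converges far inside that tolerance.

## 6. Known limitations

* No GPU path and no compiled code: training beyond a few thousand
  patients or image sides beyond ~32 pixels becomes slow.
* The genomic encoder is a transformer; no graph-structured alternative
  over gene–gene interactions is provided (none is specified well
  enough to build without guessing).
* The attention mechanism adapts per patient via content scores; it
  cannot model per-patient reliability that is invisible in the
  embedding content.
* Uncertainty is epistemic-by-dropout only; no deep ensembles,
  conformal sets, or referral thresholds.
* The policy module is tabular (an embedding-state variant would bridge
  the fusion model into the MDP state, but observational off-policy
  evaluation on clinical data is explicitly out of scope).
* `runAblation` trains every variant on the same split of the same
  cohort; it quantifies component contributions under the generator's
  assumptions, not on real data.
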
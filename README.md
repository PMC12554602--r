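# OncoFusion

Attention-based multimodal fusion, uncertainty quantification and
treatment-policy learning for oncology cohorts, in R.

## The problem

Cancer diagnosis increasingly draws on three very different data streams
per patient: imaging (histopathology, radiology), genomic profiles, and
structured clinical covariates. Models that use a single stream waste
evidence; models that naively concatenate streams cannot say *which*
stream drove a prediction, cannot cope with a missing stream, degrade
under acquisition shift between hospitals, and give no account of their
own confidence. OncoFusion implements, end to end and in pure R, a
multimodal diagnostic framework that addresses each of these:

* **Modality-specific encoders** map each stream into a shared latent
  space R^d: a strided CNN with global average pooling for the image
  `X ∈ R^(H×W×C)`, a multi-head self-attention encoder (sinusoidal
  positional encoding, `softmax(QKᵀ/√d_k)V`) for the genomic token
  sequence `g ∈ {0..V−1}^m`, and an MLP for the clinical vector
  `c ∈ R^p`. A triplet margin loss
  `max(0, τ + ‖Z_a − Z⁺‖² − ‖Z_a − Z⁻‖²)` aligns the per-patient
  embeddings across modalities.
* **Attention fusion**: scores `e_i = wᵀZ_i`, convex weights
  `α = softmax(e)` restricted to the *present* modalities (absent ones
  get exactly zero weight — no imputation), fused representation
  `Z_fused = Σ_i α_i Z_i`, classifier
  `ŷ = softmax(W_out Z_fused + b_out)`, objective
  `L = CE(ŷ, y) + λ‖w‖² + β‖W_out‖²_F` plus weighted auxiliary terms.
  Modality dropout during training enforces redundancy.
* **Adversarial domain adaptation**: a discriminator `D` and the
  encoders play the minimax game
  `L_DA = E_s log D(Z) + E_t log(1 − D(Z))` in alternating updates,
  aligning source and target feature distributions; a Gaussian-kernel
  MMD diagnostic and a paired source/target consistency penalty
  `E‖f(x_s) − f(x_t)‖²` complete the module.
* **Uncertainty**: MC-dropout predictive distributions
  (`ŷ = (1/T) Σ_t f_{θ_t}(x)` with dropout live at test time),
  per-modality variances `σ_i²` from unimodal MC probes,
  inverse-variance weights `w_i = (1/σ_i²)/Σ_j(1/σ_j²)` as an
  alternative fusion rule, and an entropy-matching calibration loss
  `L_cal = |H(ŷ) − A(α)|` (normalized) that makes the model uncertain
  exactly when its attention is diffuse.
* **Treatment policy**: a tabular Q-learner with experience replay,
  target network, ε-greedy exploration and entropy-regularized TD loss
  `E[(Q(s,a) − (r + γ max_a′ Q(s′,a′)))²] − λ_H H(π)`, validated
  against a value-iteration oracle on a bundled toy oncology MDP.

Because the real cohorts such a model targets cannot ship with a
package, OncoFusion includes a seeded synthetic cohort generator with
controllable per-modality informativeness, noise, source/target
covariate shift and modality missingness; every claim in the test suite
is made against those known ground-truth conditions.

## Worked example

```r
library(OncoFusion)

cfg <- cohortConfig(nPatients = 200, nClasses = 2,
                    informativeness = c(0.2, 0.4, 0.9),
                    noiseSd = 1, seed = 42)
cohort <- generateCohort(cfg)
split  <- splitCohort(cohort, seed = 1)
model  <- trainFusionModel(split$train, encoderConfig(),
                           trainConfig(epochs = 8, batchSize = 32, lr = 0.01),
                           seed = 1)
evaluateModel(model, split$test)
#> MetricsReport (n=30): accuracy 1.0000, macro recall 1.0000,
#>   macro F1 1.0000, macro AUC 1.0000

patient <- split$test[[1]]
predictPatient(model, patient)
#> FusionOutput
#>   alpha: image=0.001, genomic=0.001, clinical=0.998
#>   predicted class: 0 (p=1.000)

sigma2 <- modalityVariance(model, patient, T = 20, seed = 9)
round(inverseVarianceWeights(sigma2), 3)
#>    image  genomic clinical
#>        0        0        1
```

The cohort was built so the clinical stream carries most of the class
signal (informativeness 0.9 against 0.2/0.4): after training, the
attention weights concentrate on the clinical modality (α ≈ 0.998), the
held-out metrics are perfect at this noise level, and the
inverse-variance weights — computed independently of the attention
pathway, from MC-dropout variances of unimodal predictions — agree that
the clinical stream is the reliable one. `attentionReport()` emits the
same information per patient as machine-readable JSON, with
gradient-×-input saliency per modality.

The treatment-policy module is exercised the same way:

```r
mdp <- toyOncologyMdp()
res <- trainQLearning(mdp, policyConfig(episodes = 2000, seed = 1))
max(abs(res$Q - valueIteration(mdp)))   # distance to the oracle optimum
```

A thin command-line front end over these functions is installed at
`inst/cli/oncofuse.R` (verbs: `generate`, `train`, `evaluate`,
`predict`, `ablate`, `policy-train`, `diag-mmd`).

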
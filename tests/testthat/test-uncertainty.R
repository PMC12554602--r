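test_that("MC dropout collapses correctly in the degenerate regimes", {
  cfg <- tinyCohortConfig(nPatients = 6L, seed = 3L)
  co <- generateCohort(cfg)
  s <- co[[1]]
  ## dropout rate 0: zero variance, mean equals the deterministic pass
  m0 <- oncoModel(cfg, tinyEncoderConfig(dropout = 0), deskTrainConfig(),
                  seed = 2L)
  est <- mcDropoutPredict(m0, s, T = 10L, seed = 5L)
  expect_identical(est@variance, numeric(2))
  expect_equal(est@mean, predictPatient(m0, s)@probabilities,
               tolerance = 1e-12)
  ## T = 1: variance identically zero by definition
  m <- oncoModel(cfg, tinyEncoderConfig(dropout = 0.5), deskTrainConfig(),
                 seed = 2L)
  expect_identical(mcDropoutPredict(m, s, T = 1L, seed = 5L)@variance,
                   numeric(2))
  ## fixed seed: bit-identical estimates across calls
  a <- mcDropoutPredict(m, s, T = 20L, seed = 9L)
  b <- mcDropoutPredict(m, s, T = 20L, seed = 9L)
  expect_identical(a@mean, b@mean)
  expect_identical(a@variance, b@variance)
  expect_identical(a@entropy, b@entropy)
  ## the mean is a probability vector; variances are nonnegative
  expect_lt(abs(sum(a@mean) - 1), 1e-9)
  expect_true(all(a@variance >= 0))
  expect_error(mcDropoutPredict(m, s, T = 0L), "T")
})

test_that("per-modality variances drive the weighting as documented", {
  cfg <- tinyCohortConfig(nPatients = 6L, seed = 3L)
  co <- generateCohort(cfg)
  s <- co[[1]]
  ## dropout 0: all variances zero, equal-weight fallback
  m0 <- oncoModel(cfg, tinyEncoderConfig(dropout = 0), deskTrainConfig(),
                  seed = 2L)
  s2 <- modalityVariance(m0, s, T = 5L, seed = 1L)
  expect_identical(unname(s2), rep(0, 3))
  expect_equal(unname(inverseVarianceWeights(s2)), rep(1 / 3, 3))
  ## a single present modality takes weight 1 whatever its variance
  m <- oncoModel(cfg, tinyEncoderConfig(dropout = 0.4), deskTrainConfig(),
                 seed = 2L)
  sOne <- maskAllBut(s, "clinical")
  v1 <- modalityVariance(m, sOne, T = 10L, seed = 1L)
  expect_identical(v1[["image"]], Inf)
  expect_identical(v1[["genomic"]], Inf)
  w1 <- inverseVarianceWeights(v1)
  expect_equal(w1[["clinical"]], 1)
  ## seeded repetition is exact
  expect_identical(modalityVariance(m, s, T = 10L, seed = 4L),
                   modalityVariance(m, s, T = 10L, seed = 4L))
})

test_that("inverse-variance weights match the closed form", {
  expect_equal(unname(inverseVarianceWeights(c(1, 4))), c(0.8, 0.2),
               tolerance = 1e-12)
  expect_equal(unname(inverseVarianceWeights(c(2, 2, 2, 2))), rep(0.25, 4))
  expect_equal(unname(inverseVarianceWeights(c(1, Inf, Inf))), c(1, 0, 0))
  expect_error(inverseVarianceWeights(c(Inf, Inf)), "infinite")
  expect_error(inverseVarianceWeights(c(-1, 2)), "nonnegative")
  ## closed form on 1000 random positive vectors
  set.seed(14)
  for (rep in 1:1000) {
    k <- sample(2:5, 1)
    s2 <- runif(k, 0.01, 10)
    w <- inverseVarianceWeights(s2)
    expect_equal(unname(w), (1 / s2) / sum(1 / s2), tolerance = 1e-12)
    expect_true(all(w >= 0))
    expect_lt(abs(sum(w) - 1), 1e-9)
  }
  ## monotonicity: inflating one variance strictly deflates its weight
  s2 <- c(1, 2, 3)
  w <- inverseVarianceWeights(s2)
  s2b <- s2; s2b[2] <- s2[2] * 1.5
  expect_lt(inverseVarianceWeights(s2b)[2], w[2])
})

test_that("uncertainty-weighted fusion mirrors the fuse contract", {
  expect_identical(
    uncertaintyWeightedFuse(list(c(1, 2), c(3, 4), c(5, 6)), c(1, 0, 0)),
    c(1, 2))
  z <- c(2, -1)
  expect_equal(uncertaintyWeightedFuse(list(z, z, z), rep(1 / 3, 3)), z)
  expect_equal(
    uncertaintyWeightedFuse(list(c(2, 0), c(0, 2)), c(0.8, 0.2)),
    c(1.6, 0.4), tolerance = 1e-12)
  expect_error(uncertaintyWeightedFuse(list(c(1, 2)), c(0.5, 0.5)),
               "match")
  expect_error(uncertaintyWeightedFuse(list(c(1, 2), c(1, 2)),
                                       c(0.7, 0.7)), "convex")
})

test_that("entropies follow the Shannon formula and its conventions", {
  expect_identical(predictionEntropy(c(0, 1, 0)), 0)
  expect_equal(predictionEntropy(rep(0.25, 4)), log(4), tolerance = 1e-12)
  expect_equal(predictionEntropy(rep(0.25, 4), normalized = TRUE), 1,
               tolerance = 1e-12)
  ## permutation invariance
  p <- c(0.1, 0.2, 0.7)
  expect_equal(attentionEntropy(p), attentionEntropy(rev(p)),
               tolerance = 1e-12)
  expect_error(attentionEntropy(c(-0.1, 1.1)), "nonnegative")
})

test_that("the calibration loss vanishes exactly when entropies match", {
  ## uniform prediction against uniform attention, any K and M
  for (K in 2:5) for (M in 2:4)
    expect_lt(calibrationLoss(rep(1 / K, K), rep(1 / M, M)), 1e-12)
  ## one-hot against one-hot
  expect_identical(calibrationLoss(c(1, 0, 0), c(0, 1)), 0)
  ## uniform over 2 (normalized entropy 1) vs one-hot attention (0)
  expect_equal(calibrationLoss(c(0.5, 0.5), c(1, 0, 0)), 1,
               tolerance = 1e-12)
  ## bounded in [0, 1] and positive on mismatched random pairs
  set.seed(6)
  for (rep in 1:200) {
    K <- sample(2:5, 1); M <- sample(2:4, 1)
    p <- exp(rnorm(K)); p <- p / sum(p)
    a <- exp(rnorm(M)); a <- a / sum(a)
    l <- calibrationLoss(p, a)
    expect_gte(l, 0)
    expect_lte(l, 1)
    hn <- predictionEntropy(p, normalized = TRUE)
    an <- attentionEntropy(a, normalized = TRUE)
    if (abs(hn - an) > 1e-9) expect_gt(l, 0)
  }
})

test_that("fusion strategies share the attention pathway embeddings", {
  cfg <- tinyCohortConfig(nPatients = 20L, seed = 8L, noiseSd = 0.6)
  co <- generateCohort(cfg)
  m <- trainFusionModel(co, tinyEncoderConfig(dropout = 0.3),
                        deskTrainConfig(epochs = 2L), seed = 1L)
  s <- co[[1]]
  att <- predictWithStrategy(m, s, "attention")
  expect_equal(att$probabilities, predictPatient(m, s)@probabilities,
               tolerance = 1e-12)
  iv <- predictWithStrategy(m, s, "inverse_variance", T = 10L, seed = 3L)
  expect_lt(abs(sum(iv$weights[c("image", "genomic", "clinical")]) - 1),
            1e-9)
  expect_lt(abs(sum(iv$probabilities) - 1), 1e-9)
  pr <- predictWithStrategy(m, s, "product", T = 10L, seed = 3L)
  expect_lt(abs(sum(pr$weights[c("image", "genomic", "clinical")]) - 1),
            1e-9)
})
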
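test_that("scaled dot-product attention matches its degenerate cases", {
  ## one token: softmax of a single score is 1, output equals the V row
  Q <- matrix(rnorm(3), 1); K <- matrix(rnorm(3), 1)
  V <- matrix(c(2, -1, 0.5), 1)
  expect_equal(scaledDotAttention(Q, K, V, dK = 3), V)
  ## all-zero scores: uniform attention, each row is the column mean of V
  Q0 <- matrix(0, 3, 2); K0 <- matrix(0, 3, 2)
  V3 <- matrix(rnorm(9), 3)
  out <- scaledDotAttention(Q0, K0, V3, dK = 2)
  for (i in 1:3) expect_equal(out[i, ], colMeans(V3))
  expect_error(scaledDotAttention(matrix(NA_real_, 1, 1),
                                  matrix(1, 1, 1), matrix(1, 1, 1)),
               "finite")
})

test_that("attention rows are convex weights and match the brute force", {
  set.seed(42)
  for (rep in 1:25) {
    m <- sample(2:6, 1)
    dk <- sample(1:4, 1)
    Q <- matrix(rnorm(m * dk), m); K <- matrix(rnorm(m * dk), m)
    V <- matrix(rnorm(m * 3), m)
    got <- scaledDotAttention(Q, K, V, dK = dk)
    expect_equal(got, bruteForceAttention(Q, K, V, dk), tolerance = 1e-6)
    ## weights themselves: recompute and check convexity
    A <- exp(Q %*% t(K) / sqrt(dk))
    A <- A / rowSums(A)
    expect_true(all(A >= 0))
    expect_equal(rowSums(A), rep(1, m), tolerance = 1e-9)
  }
})

test_that("the image encoder satisfies its contracts", {
  cfg <- tinyCohortConfig()
  m <- tinyModel(cfg)
  x <- array(rnorm(36), dim = c(6, 6, 1))
  e1 <- encodeImage(x, m, "p1")
  expect_s4_class(e1, "ModalityEmbedding")
  expect_length(e1@vector, 8L)
  expect_true(all(is.finite(e1@vector)))
  ## determinism
  expect_identical(encodeImage(x, m)@vector, e1@vector)
  ## linearity through zero: all-zero input with zero biases
  z <- encodeImage(array(0, dim = c(6, 6, 1)), m)
  expect_identical(z@vector, numeric(8L))
  ## shape mismatch names expected and actual
  expect_error(encodeImage(array(0, dim = c(5, 6, 1)), m), "6x6x1")
})

test_that("the genomic encoder pools, errors on OOV and is deterministic", {
  cfg <- tinyCohortConfig()
  m <- tinyModel(cfg)
  g <- c(0L, 3L, 5L, 1L, 2L, 4L, 0L, 1L)
  e <- encodeGenomic(g, m)
  expect_length(e@vector, 8L)
  expect_identical(encodeGenomic(g, m)@vector, e@vector)
  ## out-of-vocabulary token reports the position
  expect_error(encodeGenomic(c(0L, 9L, 1L, 0L, 0L, 0L, 0L, 0L), m),
               "position 2")
  ## length-1 sequence: pooling over one token is the identity
  cfg1 <- cohortConfig(nPatients = 2L, imageShape = c(6L, 6L, 1L),
                       genomicLength = 1L, vocabSize = 6L,
                       clinicalDim = 4L, seed = 1L)
  m1 <- oncoModel(cfg1, tinyEncoderConfig(), deskTrainConfig(), seed = 2L)
  expect_length(encodeGenomic(0L, m1)@vector, 8L)
})

test_that("positional encoding controls permutation sensitivity", {
  cfg <- tinyCohortConfig()
  g <- c(0L, 3L, 5L, 1L, 2L, 4L, 0L, 1L)
  gp <- rev(g)
  mPE <- oncoModel(cfg, tinyEncoderConfig(genomicPosEncoding = TRUE),
                   deskTrainConfig(), seed = 5L)
  mNoPE <- oncoModel(cfg, tinyEncoderConfig(genomicPosEncoding = FALSE),
                     deskTrainConfig(), seed = 5L)
  ## with positions encoded, order matters
  expect_gt(max(abs(encodeGenomic(g, mPE)@vector -
                      encodeGenomic(gp, mPE)@vector)), 1e-8)
  ## without positions and with mean pooling, order is irrelevant
  expect_equal(encodeGenomic(g, mNoPE)@vector,
               encodeGenomic(gp, mNoPE)@vector, tolerance = 1e-12)
})

test_that("the clinical encoder matches its closed forms", {
  cfg <- tinyCohortConfig()
  ## single linear layer, identity activation: exactly W c + b
  mLin <- oncoModel(cfg, tinyEncoderConfig(clinicalHidden = integer(),
                                           activation = "identity"),
                    deskTrainConfig(), seed = 3L)
  cvec <- rnorm(4)
  expected <- as.numeric(modelParams(mLin)$clin_W_1 %*% cvec) +
    modelParams(mLin)$clin_b_1
  expect_equal(encodeClinical(cvec, mLin)@vector, expected,
               tolerance = 1e-12)
  ## zero input, zero bias, ReLU: zero embedding
  m <- tinyModel(cfg)
  expect_identical(encodeClinical(numeric(4), m)@vector, numeric(8))
  ## dropout disabled in deterministic mode: repeated calls identical
  expect_identical(encodeClinical(cvec, m)@vector,
                   encodeClinical(cvec, m)@vector)
  expect_error(encodeClinical(rnorm(3), m), "length 3")
})

test_that("the contrastive alignment loss follows the triplet ordering", {
  ## hand evaluation: tau 1, d+ = 0.5, d- = 0.2 => 1 + 0.5 - 0.2 = 1.3
  a <- c(0, 0); p <- c(sqrt(0.5), 0); n <- c(0, sqrt(0.2))
  expect_equal(contrastiveAlignmentLoss(a, p, n, margin = 1), 1.3)
  ## margin satisfied: anchor == positive, negative far away
  far <- c(2, 0)
  expect_identical(contrastiveAlignmentLoss(a, a, far, margin = 1), 0)
  ## tau = 0 with positive == negative: both modes cancel
  expect_identical(contrastiveAlignmentLoss(a, p, p, margin = 0), 0)
  expect_identical(contrastiveAlignmentLoss(a, p, p, margin = 0,
                                            literal = TRUE), 0)
  ## the literal (printed) convention swaps the distances
  expect_equal(contrastiveAlignmentLoss(a, p, n, margin = 1,
                                        literal = TRUE),
               max(0, 1 + 0.2 - 0.5))
  ## nonnegativity and monotonicity in the margin
  set.seed(9)
  for (rep in 1:50) {
    v <- replicate(3, rnorm(4), simplify = FALSE)
    t1 <- runif(1, 0, 2); t2 <- t1 + runif(1, 0, 2)
    l1 <- contrastiveAlignmentLoss(v[[1]], v[[2]], v[[3]], t1)
    l2 <- contrastiveAlignmentLoss(v[[1]], v[[2]], v[[3]], t2)
    expect_gte(l1, 0)
    expect_gte(l2, l1)
  }
  expect_error(contrastiveAlignmentLoss(c(1, 2), c(1, 2, 3), c(1, 2), 1),
               "equal length")
})
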
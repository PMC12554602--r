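mkEmb <- function(v, modality = "image", present = TRUE)
  new("ModalityEmbedding", vector = v, modality = modality,
      patientId = "p", present = present)

test_that("modality attention produces masked softmax weights", {
  z <- list(mkEmb(c(1, 0), "image"), mkEmb(c(0, 1), "genomic"),
            mkEmb(c(1, 1), "clinical"))
  ## zero attention vector: uniform over the present modalities
  a <- modalityAttention(z, w = c(0, 0))
  expect_equal(unname(a$alpha), rep(1 / 3, 3), tolerance = 1e-12)
  ## scores (ln 2, 0): weights (2/3, 1/3)
  z2 <- list(mkEmb(c(log(2), 0)), mkEmb(c(0, 0), "genomic"))
  a2 <- modalityAttention(z2, w = c(1, 0))
  expect_equal(unname(a2$alpha), c(2 / 3, 1 / 3), tolerance = 1e-9)
  ## absent modality: weight exactly 0, remaining uniform
  z3 <- list(mkEmb(c(1, 0)), mkEmb(c(0, 1), "genomic"),
             mkEmb(c(9, 9), "clinical", present = FALSE))
  a3 <- modalityAttention(z3, w = c(0, 0))
  expect_equal(unname(a3$alpha), c(0.5, 0.5, 0), tolerance = 1e-12)
  ## no present modality at all is an error
  z4 <- list(mkEmb(c(1, 0), present = FALSE))
  expect_error(modalityAttention(z4, w = c(0, 0)), "present")
})

test_that("fusion is the stated convex combination", {
  z1 <- c(1, 0); z2 <- c(0, 1); z3 <- c(3, 3)
  expect_identical(fuseEmbeddings(list(z1, z2, z3), c(1, 0, 0)), z1)
  ## convexity fixed point: identical embeddings map to themselves
  expect_equal(fuseEmbeddings(list(z3, z3, z3), c(0.2, 0.5, 0.3)), z3)
  expect_equal(fuseEmbeddings(list(z1, z2), c(0.25, 0.75)), c(0.25, 0.75))
  expect_error(fuseEmbeddings(list(c(1, 2), c(1, 2, 3)), c(0.5, 0.5)),
               "inconsistent")
})

test_that("fused vectors stay in the convex hull of present inputs", {
  set.seed(31)
  for (rep in 1:1000) {
    d <- sample(2:5, 1)
    k <- sample(2:4, 1)
    zs <- replicate(k, rnorm(d), simplify = FALSE)
    e <- rnorm(k)
    alpha <- exp(e) / sum(exp(e))
    expect_true(all(alpha >= 0))
    expect_lt(abs(sum(alpha) - 1), 1e-9)
    zf <- fuseEmbeddings(zs, alpha)
    zmat <- do.call(rbind, zs)
    expect_true(all(zf >= apply(zmat, 2, min) - 1e-9))
    expect_true(all(zf <= apply(zmat, 2, max) + 1e-9))
  }
})

test_that("the classifier head is a shifted-softmax linear map", {
  cfg <- cohortConfig(nPatients = 2L, nClasses = 4L, seed = 1L,
                      imageShape = c(6L, 6L, 1L), genomicLength = 8L,
                      vocabSize = 6L, clinicalDim = 4L)
  m <- oncoModel(cfg, tinyEncoderConfig(), deskTrainConfig(), seed = 2L)
  m@params$out_W <- matrix(0, 4, 8)
  m@params$out_b <- numeric(4)
  out <- classifyFused(rnorm(8), m)
  expect_equal(out$probabilities, rep(0.25, 4), tolerance = 1e-12)
  ## logits (ln 1, ln 3) -> (0.25, 0.75)
  m2 <- oncoModel(tinyCohortConfig(), tinyEncoderConfig(),
                  deskTrainConfig(), seed = 2L)
  m2@params$out_W <- matrix(0, 2, 8)
  m2@params$out_b <- c(log(1), log(3))
  expect_equal(classifyFused(numeric(8), m2)$probabilities, c(0.25, 0.75),
               tolerance = 1e-12)
  ## shift invariance of the softmax
  m2@params$out_b <- c(log(1), log(3)) + 17.3
  expect_equal(classifyFused(numeric(8), m2)$probabilities, c(0.25, 0.75),
               tolerance = 1e-12)
})

test_that("the training loss assembles its documented parts", {
  ## one-hot on the true class, no regularization: loss 0
  expect_equal(trainingLoss(c(0, 1, 0), 1L), 0, tolerance = 1e-9)
  ## uniform over 4 classes: ln 4
  expect_equal(trainingLoss(rep(0.25, 4), 2L), log(4), tolerance = 1e-12)
  ## attention penalty: lambda ||w||^2 with w = (3, 4) adds 25
  expect_equal(trainingLoss(c(1, 0), 0L, w = c(3, 4), lambda = 1), 25,
               tolerance = 1e-9)
  ## mean reduction over a batch
  pm <- rbind(c(0.5, 0.5), c(0.25, 0.75))
  expect_equal(trainingLoss(pm, c(0L, 1L)),
               mean(-log(c(0.5, 0.75))), tolerance = 1e-12)
  ## auxiliary losses enter with their weights
  expect_equal(trainingLoss(c(1, 0), 0L, auxLosses = c(cal = 0.5),
                            auxWeights = 0.1), 0.05, tolerance = 1e-12)
  ## epsilon clipping keeps a zero true-class probability finite
  expect_true(is.finite(trainingLoss(c(1, 0), 1L)))
  ## nonnegative whenever all weights are nonnegative
  set.seed(8)
  for (rep in 1:100) {
    K <- sample(2:5, 1)
    p <- exp(rnorm(K)); p <- p / sum(p)
    l <- trainingLoss(p, sample(0:(K - 1L), 1), w = rnorm(3),
                      Wout = matrix(rnorm(6), 2), lambda = runif(1),
                      beta = runif(1), auxLosses = runif(2),
                      auxWeights = runif(2))
    expect_gte(l, 0)
  }
})

test_that("modality dropout keeps at least one stream", {
  z <- list(mkEmb(c(1, 0), "image"), mkEmb(c(0, 1), "genomic"),
            mkEmb(c(1, 1), "clinical"))
  ## rate 0 is the identity
  expect_identical(modalityDropout(z, 0, seed = 1L), z)
  ## a single present modality is always retained
  zOne <- list(mkEmb(c(1, 0), "image"),
               mkEmb(c(0, 1), "genomic", present = FALSE),
               mkEmb(c(1, 1), "clinical", present = FALSE))
  for (s in 1:25) {
    out <- modalityDropout(zOne, 0.9, seed = s)
    expect_true(out[[1]]@present)
  }
  expect_error(modalityDropout(z, 1), "rate")
  ## drop frequency matches the post-restoration expectation
  ## rate - rate^3 / 3 over many seeded trials
  rate <- 0.5
  nTrial <- 10000L
  dropped <- 0L
  set.seed(123)
  for (i in seq_len(nTrial)) {
    keep <- OncoFusion:::dropPresentMask(rep(TRUE, 3), rate)
    dropped <- dropped + sum(!keep)
  }
  pAbs <- rate - rate^3 / 3
  se <- sqrt(pAbs * (1 - pAbs) / (3 * nTrial))
  expect_lt(abs(dropped / (3 * nTrial) - pAbs), 3 * se)
})

test_that("end-to-end training meets its contract and learns a
          separable cohort", {
  cfg <- tinyCohortConfig(nPatients = 10L, seed = 4L)
  co <- generateCohort(cfg)
  m <- trainFusionModel(co, tinyEncoderConfig(),
                        deskTrainConfig(epochs = 1L), seed = 1L)
  expect_identical(nrow(trainingLog(m)), 1L)
  expect_true(is.finite(trainingLog(m)$loss))
  ## identical seeds give identical parameters
  m2 <- trainFusionModel(co, tinyEncoderConfig(),
                         deskTrainConfig(epochs = 1L), seed = 1L)
  expect_identical(modelParams(m), modelParams(m2))

  ## clinical-only signal, n = 200: a plain logistic fit on the raw
  ## clinical features separates the classes (independent oracle), and so
  ## must the trained fusion model
  cfgSep <- tinyCohortConfig(nPatients = 200L, seed = 11L,
                             informativeness = c(0, 0, 1), noiseSd = 0.5)
  coSep <- generateCohort(cfgSep)
  lab <- vapply(samples(coSep), function(s) s@label, integer(1))
  clin <- t(vapply(samples(coSep), function(s) s@clinical, numeric(4)))
  fit <- suppressWarnings(
    stats::glm(lab ~ clin, family = stats::binomial()))
  oracleAcc <- mean((stats::fitted(fit) > 0.5) == (lab == 1L))
  expect_gt(oracleAcc, 0.9)
  mSep <- trainFusionModel(coSep, tinyEncoderConfig(),
                           deskTrainConfig(epochs = 10L), seed = 1L)
  acc <- mean(vapply(samples(coSep), function(s)
    which.max(predictPatient(mSep, s)@probabilities) - 1L == s@label,
    logical(1)))
  expect_gt(acc, 0.9)
})

test_that("self-reconstruction heads train and shrink their loss", {
  cfg <- tinyCohortConfig(nPatients = 40L, seed = 12L, noiseSd = 0.3)
  co <- generateCohort(cfg)
  m <- trainFusionModel(co, tinyEncoderConfig(),
                        deskTrainConfig(epochs = 6L,
                                        reconstructionWeight = 0.5),
                        seed = 1L)
  expect_true(all(c("rec_W_image", "rec_W_genomic", "rec_W_clinical") %in%
                    names(modelParams(m))))
  lg <- trainingLog(m)
  expect_true(all(is.finite(lg$reconstruction)))
  expect_lt(lg$reconstruction[6L], lg$reconstruction[1L])
})

test_that("training aborts with a diagnostic on divergence", {
  co <- generateCohort(tinyCohortConfig(nPatients = 12L, seed = 4L))
  expect_error(
    trainFusionModel(co, tinyEncoderConfig(),
                     deskTrainConfig(epochs = 3L, lr = 1e160)),
    "diverged|non-finite")
})
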
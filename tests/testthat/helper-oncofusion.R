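## Shared fixtures and independent oracles for the test suite.

## A small, fast cohort configuration; all dimensions shrunk so that every
## encoder still has real work to do.
tinyCohortConfig <- function(nPatients = 20L, nClasses = 2L, seed = 7L,
                             ...) {
  cohortConfig(nPatients = nPatients, imageShape = c(6L, 6L, 1L),
               genomicLength = 8L, vocabSize = 6L, clinicalDim = 4L,
               nClasses = nClasses, seed = seed, ...)
}

tinyEncoderConfig <- function(...) {
  args <- utils::modifyList(
    list(d = 8L, imageChannels = c(3L), genomicEmbDim = 8L,
         genomicHeads = 2L, genomicLayers = 1L, genomicDk = 4L,
         clinicalHidden = c(6L)),
    list(...))
  do.call(encoderConfig, args)
}

## Desk-scale optimizer settings used throughout the suite.
deskTrainConfig <- function(...) {
  args <- utils::modifyList(
    list(epochs = 4L, batchSize = 16L, lr = 0.01), list(...))
  do.call(trainConfig, args)
}

tinyModel <- function(cfg = tinyCohortConfig(), enc = tinyEncoderConfig(),
                      train = deskTrainConfig(), seed = 1L) {
  oncoModel(cfg, enc, train, seed = seed)
}

## Independent nested-loop oracle for scaled dot-product attention.
bruteForceAttention <- function(Q, K, V, dk) {
  out <- matrix(0, nrow(Q), ncol(V))
  for (i in seq_len(nrow(Q))) {
    s <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) {
      acc <- 0
      for (c in seq_len(ncol(Q))) acc <- acc + Q[i, c] * K[j, c]
      s[j] <- acc / sqrt(dk)
    }
    w <- exp(s - max(s)); w <- w / sum(w)
    for (j in seq_len(nrow(V))) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

## Independent nested-loop oracle for the biased Gaussian-kernel MMD.
bruteForceMMD <- function(Zs, Zt, bw) {
  kern <- function(x, y) exp(-sum((x - y)^2) / (2 * bw^2))
  acc <- function(A, B) {
    s <- 0
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
      s <- s + kern(A[i, ], B[j, ])
    s / (nrow(A) * nrow(B))
  }
  acc(Zs, Zs) + acc(Zt, Zt) - 2 * acc(Zs, Zt)
}

## Mark all but one modality absent on a copy of a sample.
maskAllBut <- function(sample, keep) {
  mask <- stats::setNames(c("image", "genomic", "clinical") == keep,
                          c("image", "genomic", "clinical"))
  sample@modalityMask <- mask
  sample
}

## Mean attention weights of a trained model over a cohort.
meanAttention <- function(model, cohort) {
  a <- vapply(samples(cohort), function(s)
    alphaWeights(predictPatient(model, s)), numeric(3))
  rowMeans(a)
}
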
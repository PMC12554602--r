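#' Softmax attention weights over present modalities
#'
#' Scores each present modality embedding with the learned attention vector,
#' \eqn{e_i = w^\top Z_i}, and normalizes with a softmax restricted to the
#' present modalities, so the weights form a convex combination and absent
#' modalities receive exactly zero weight (no imputation).
#'
#' @param embeddings list of \linkS4class{ModalityEmbedding} (or plain
#'   numeric vectors, all assumed present).
#' @param w length-d attention vector.
#' @return list with \code{alpha} (named weights, 0 for absent) and
#'   \code{scores} (raw \eqn{e_i}, NA for absent).
#' @export
#' @examples
#' z <- list(c(1, 0), c(0, 1), c(1, 1))
#' modalityAttention(z, w = c(0, 0))$alpha  # uniform: 1/3 each
modalityAttention <- function(embeddings, w) {
  vecs <- lapply(embeddings, asEmbeddingVector)
  present <- vapply(embeddings, function(e)
    if (is(e, "ModalityEmbedding")) e@present else TRUE, logical(1))
  nm <- vapply(seq_along(embeddings), function(i) {
    e <- embeddings[[i]]
    if (is(e, "ModalityEmbedding") && nzchar(e@modality)) e@modality
    else paste0("m", i)
  }, character(1))
  if (!any(present)) stop("no present modality to attend over")
  scores <- rep(NA_real_, length(vecs))
  scores[present] <- vapply(vecs[present], function(z) sum(w * z), numeric(1))
  alpha <- numeric(length(vecs))
  alpha[present] <- softmaxVec(scores[present])
  names(alpha) <- nm
  names(scores) <- nm
  list(alpha = alpha, scores = scores)
}

#' Fuse modality embeddings with convex weights
#'
#' \eqn{Z_{fused} = \sum_i \alpha_i Z_i} over present modalities.  The same
#' contract serves attention weights and inverse-variance weights.
#'
#' @param embeddings list of \linkS4class{ModalityEmbedding} or numeric
#'   vectors.
#' @param alpha weight vector aligned with \code{embeddings} (weights of
#'   absent modalities must be 0).
#' @return fused numeric vector.
#' @export
fuseEmbeddings <- function(embeddings, alpha) {
  vecs <- lapply(embeddings, asEmbeddingVector)
  d <- unique(vapply(vecs, length, integer(1)))
  if (length(d) != 1L)
    stop("embeddings have inconsistent lengths: ",
         paste(vapply(vecs, length, integer(1)), collapse = ", "))
  if (length(alpha) != length(vecs))
    stop("length(alpha) must match the number of embeddings")
  z <- numeric(d)
  for (i in seq_along(vecs)) if (alpha[i] != 0) z <- z + alpha[i] * vecs[[i]]
  z
}

#' Classify a fused representation
#'
#' \eqn{\hat y = \mathrm{softmax}(W_{out} Z_{fused} + b_{out})}.
#'
#' @param zFused fused length-d vector.
#' @param model an \linkS4class{OncoModel} (its classifier head is used).
#' @return list with \code{logits} and \code{probabilities}.
#' @export
classifyFused <- function(zFused, model) {
  if (any(!is.finite(zFused))) stop("zFused must be finite")
  logits <- as.numeric(model@params$out_W %*% zFused) + model@params$out_b
  list(logits = logits, probabilities = softmaxVec(logits))
}

#' Regularized training loss
#'
#' Cross-entropy of the predicted probabilities against the true labels
#' plus the structured penalty \eqn{\lambda\|w\|^2 + \beta\|W_{out}\|_F^2}
#' on the attention vector and classifier head, plus a weighted sum of any
#' enabled auxiliary losses.  Cross-entropy probabilities are clipped at
#' \code{epsClip} to guard against exact zeros.  With a matrix of
#' predictions the cross-entropy is averaged over rows (mean reduction).
#'
#' @param probs probability vector, or matrix with one row per sample.
#' @param y 0-based class index (vector for matrix input).
#' @param w attention vector (for the \eqn{\lambda} penalty).
#' @param Wout classifier weight matrix (for the \eqn{\beta} penalty).
#' @param lambda,beta nonnegative regularization weights.
#' @param auxLosses named numeric vector of auxiliary loss values.
#' @param auxWeights matching nonnegative weights.
#' @param epsClip floor applied to the true-class probability.
#' @return scalar loss.
#' @export
#' @examples
#' trainingLoss(rep(0.25, 4), 1L)            # ln 4
#' trainingLoss(c(1, 0), 0L, w = c(3, 4), lambda = 1)  # 25
trainingLoss <- function(probs, y, w = NULL, Wout = NULL, lambda = 0,
                         beta = 0, auxLosses = numeric(), auxWeights = NULL,
                         epsClip = 1e-12) {
  if (lambda < 0 || beta < 0) stop("'lambda' and 'beta' must be >= 0")
  pm <- if (is.matrix(probs)) probs else matrix(probs, nrow = 1L)
  y <- as.integer(y)
  if (length(y) != nrow(pm)) stop("length(y) must match predictions")
  if (any(y < 0L | y >= ncol(pm))) stop("class index out of range")
  ptrue <- pm[cbind(seq_len(nrow(pm)), y + 1L)]
  ce <- mean(-log(pmax(ptrue, epsClip)))
  reg <- 0
  if (!is.null(w)) reg <- reg + lambda * sum(w^2)
  if (!is.null(Wout)) reg <- reg + beta * sum(Wout^2)
  aux <- 0
  if (length(auxLosses)) {
    if (is.null(auxWeights)) auxWeights <- rep(1, length(auxLosses))
    if (any(auxWeights < 0)) stop("auxiliary weights must be >= 0")
    aux <- sum(auxWeights * auxLosses)
  }
  ce + reg + aux
}

#' Randomly mask whole modalities (training-time modality dropout)
#'
#' Each present modality is independently marked absent with probability
#' \code{rate}; if every present modality would be dropped, one of them
#' (uniformly chosen, seeded) is retained, since the architecture requires
#' at least one input stream.
#'
#' @param embeddings list of \linkS4class{ModalityEmbedding}.
#' @param rate drop probability in [0, 1).
#' @param seed RNG seed.
#' @return the list with some embeddings marked \code{present = FALSE}.
#' @export
modalityDropout <- function(embeddings, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("'rate' must be in [0, 1)")
  if (rate == 0) return(embeddings)
  set.seed(seed)
  present <- vapply(embeddings, function(e) e@present, logical(1))
  keep <- dropPresentMask(present, rate)
  for (i in seq_along(embeddings)) embeddings[[i]]@present <- keep[i]
  embeddings
}

## Internal mask-level modality dropout: draws from the current RNG stream.
dropPresentMask <- function(present, rate) {
  if (rate <= 0) return(present)
  drop <- present & (stats::runif(length(present)) < rate)
  keep <- present & !drop
  if (!any(keep)) {
    cand <- which(present)
    keep[cand[sample.int(length(cand), 1L)]] <- TRUE
  }
  keep
}

## ---- full-sample forward / backward ------------------------------------

## Forward pass of the whole model on one patient.  `present` overrides the
## sample's modality mask (used by modality dropout and by per-modality
## uncertainty probing); `stochastic` activates dropout masks.
sampleForward <- function(P, cfg, spec, sample, stochastic = FALSE,
                          present = NULL) {
  if (is.null(present)) present <- sample@modalityMask
  if (!any(present)) stop("no present modality for patient ",
                          sample@patientId)
  if (cfg$style == "shared") {
    s2 <- sample
    s2@modalityMask <- stats::setNames(present, MODALITIES)
    fw <- sharedForward(sharedFlatten(s2, spec), P, cfg,
                        stochastic = stochastic)
    mask <- dropMask(length(fw$z), cfg$dropout, stochastic)
    z <- fw$z * mask
    logits <- as.numeric(P$out_W %*% z) + P$out_b
    return(list(style = "shared", enc = list(shared = fw),
                embMasks = list(shared = mask),
                z = list(shared = z), present = present,
                alpha = c(shared = 1), scores = c(shared = NA_real_),
                zf = z, logits = logits, probs = softmaxVec(logits)))
  }
  enc <- list(); z <- list(); embMasks <- list()
  if (present[["image"]]) {
    enc$image <- imgForward(sample@image, P, cfg, spec)
    embMasks$image <- dropMask(cfg$d, cfg$dropout, stochastic)
    z$image <- enc$image$z * embMasks$image
  }
  if (present[["genomic"]]) {
    enc$genomic <- genForward(sample@genomic, P, cfg, spec)
    embMasks$genomic <- dropMask(cfg$d, cfg$dropout, stochastic)
    z$genomic <- enc$genomic$z * embMasks$genomic
  }
  if (present[["clinical"]]) {
    enc$clinical <- clinForward(sample@clinical, P, cfg, spec,
                                stochastic = stochastic)
    embMasks$clinical <- dropMask(cfg$d, cfg$dropout, stochastic)
    z$clinical <- enc$clinical$z * embMasks$clinical
  }
  pm <- MODALITIES[present[MODALITIES]]
  scoresP <- vapply(z[pm], function(zz) sum(P$fus_w * zz), numeric(1))
  alphaP <- if (identical(cfg$fusion, "uniform"))
    stats::setNames(rep(1 / length(pm), length(pm)), pm)
  else softmaxVec(scoresP)
  zf <- numeric(cfg$d)
  for (m in pm) zf <- zf + alphaP[[m]] * z[[m]]
  alpha <- stats::setNames(numeric(3L), MODALITIES)
  scores <- stats::setNames(rep(NA_real_, 3L), MODALITIES)
  alpha[pm] <- alphaP
  scores[pm] <- scoresP
  logits <- as.numeric(P$out_W %*% zf) + P$out_b
  list(style = "tailored", enc = enc, embMasks = embMasks, z = z,
       present = present, alpha = alpha, scores = scores, zf = zf,
       logits = logits, probs = softmaxVec(logits))
}

## Backward pass for one patient.  Gradient seeds:
##   dlogits     - gradient of the loss w.r.t. the classifier logits
##   dzfExtra    - extra gradient w.r.t. the fused vector (adversarial term)
##   dAlphaExtra - extra gradient w.r.t. the attention weights (calibration)
##   dZextra     - named list of extra per-modality embedding gradients
##                 (contrastive alignment)
sampleBackward <- function(fwd, P, cfg, spec, g, dlogits,
                           dzfExtra = NULL, dAlphaExtra = NULL,
                           dZextra = NULL) {
  addGrad(g, "out_W", dlogits %o% fwd$zf)
  addGrad(g, "out_b", dlogits)
  dzf <- as.numeric(t(P$out_W) %*% dlogits)
  if (!is.null(dzfExtra)) dzf <- dzf + dzfExtra

  if (fwd$style == "shared") {
    dz <- dzf
    if (!is.null(dZextra$shared)) dz <- dz + dZextra$shared
    dz <- dz * fwd$embMasks$shared
    sharedBackward(dz, fwd$enc$shared, P, cfg, g)
    return(invisible(NULL))
  }

  pm <- MODALITIES[fwd$present[MODALITIES]]
  alphaP <- fwd$alpha[pm]
  uniformFusion <- identical(cfg$fusion, "uniform")
  de <- stats::setNames(numeric(length(pm)), pm)
  if (!uniformFusion) {
    dAlpha <- vapply(pm, function(m) sum(dzf * fwd$z[[m]]), numeric(1))
    if (!is.null(dAlphaExtra)) dAlpha <- dAlpha + dAlphaExtra[pm]
    de <- alphaP * (dAlpha - sum(alphaP * dAlpha))
  }
  dw <- numeric(cfg$d)
  for (i in seq_along(pm)) {
    m <- pm[i]
    dz <- alphaP[[m]] * dzf + de[[i]] * P$fus_w
    if (!is.null(dZextra[[m]])) dz <- dz + dZextra[[m]]
    dw <- dw + de[[i]] * fwd$z[[m]]
    dz <- dz * fwd$embMasks[[m]]
    if (m == "image") imgBackward(dz, fwd$enc$image, P, cfg, g)
    else if (m == "genomic") genBackward(dz, fwd$enc$genomic, P, cfg, g)
    else clinBackward(dz, fwd$enc$clinical, P, cfg, g)
  }
  addGrad(g, "fus_w", dw)
  invisible(NULL)
}

#' Run the fusion model on one patient
#'
#' Deterministic (dropout-off) forward pass through the modality encoders,
#' attention fusion and classifier head.
#'
#' @param model an \linkS4class{OncoModel}.
#' @param sample a \linkS4class{PatientSample}.
#' @return a \linkS4class{FusionOutput}.
#' @export
predictPatient <- function(model, sample) {
  fwd <- sampleForward(model@params, model@encoderConfig, model@inputSpec,
                       sample, stochastic = FALSE)
  new("FusionOutput", zFused = fwd$zf, alpha = fwd$alpha,
      scores = fwd$scores, logits = fwd$logits,
      probabilities = fwd$probs)
}
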
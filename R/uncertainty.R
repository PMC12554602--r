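#' Monte-Carlo-dropout predictive distribution
#'
#' Runs \code{T} stochastic forward passes with all dropout sites active
#' and summarizes them: the predictive mean is the average of the \code{T}
#' probability vectors, the per-class variance is the empirical variance
#' across passes (0 when \code{T = 1}), and the entropy is the Shannon
#' entropy of the mean.  Deterministic given \code{seed}; with a dropout
#' rate of 0 every pass equals the deterministic forward pass and the
#' variance is identically 0.
#'
#' @param model an \linkS4class{OncoModel}.
#' @param sample a \linkS4class{PatientSample}.
#' @param T number of stochastic passes (>= 1).
#' @param seed RNG seed for the dropout draws.
#' @param present optional named logical overriding the sample's modality
#'   mask (used for per-modality probing).
#' @return a \linkS4class{PredictiveEstimate}.
#' @export
mcDropoutPredict <- function(model, sample, T = 20L, seed = 1L,
                             present = NULL) {
  T <- checkCount(T, "T")
  set.seed(seed)
  K <- model@inputSpec$nClasses
  probs <- matrix(0, T, K)
  for (t in seq_len(T))
    probs[t, ] <- sampleForward(model@params, model@encoderConfig,
                                model@inputSpec, sample,
                                stochastic = TRUE, present = present)$probs
  mu <- colMeans(probs)
  v <- if (T > 1L) apply(probs, 2L, stats::var) else numeric(K)
  new("PredictiveEstimate", mean = mu, variance = pmax(v, 0),
      entropy = shannonEntropy(mu), passes = T, seed = as.numeric(seed))
}

#' Per-modality predictive variance
#'
#' For each present modality, runs \code{\link{mcDropoutPredict}} on the
#' patient with all other modalities masked absent; the modality's
#' uncertainty \eqn{\sigma_i^2} is the mean over classes of the per-class
#' Monte-Carlo variance of that unimodal prediction.  Absent modalities
#' get \eqn{\sigma_i^2 = +\infty} (zero weight downstream).
#'
#' @inheritParams mcDropoutPredict
#' @param T number of stochastic passes (>= 2).
#' @return named numeric vector of per-modality variances.
#' @export
modalityVariance <- function(model, sample, T = 20L, seed = 1L) {
  if (T < 2L) stop("'T' must be >= 2 for a variance estimate")
  if (model@encoderConfig$style != "tailored")
    stop("per-modality variance requires the tailored encoders")
  if (!any(sample@modalityMask)) stop("no present modality")
  sigma2 <- stats::setNames(rep(Inf, 3L), MODALITIES)
  for (m in MODALITIES) {
    if (!sample@modalityMask[[m]]) next
    pres <- stats::setNames(MODALITIES == m, MODALITIES)
    est <- mcDropoutPredict(model, sample, T = T,
                            seed = deriveSeed(seed, match(m, MODALITIES)),
                            present = pres)
    sigma2[[m]] <- mean(est@variance)
  }
  sigma2
}

#' Inverse-variance modality weights
#'
#' \deqn{w_i = (1/\sigma_i^2) \Big/ \sum_j 1/\sigma_j^2,}
#' so lower-uncertainty modalities receive larger convex weights.  An
#' infinite variance (absent modality) yields weight 0.  If every finite
#' variance is (numerically) zero the weights fall back to equal weighting
#' over the finite entries; if some but not all are zero, the weight is
#' split equally among the zero-variance entries (the limit of the
#' formula).
#'
#' @param sigma2 numeric vector of per-modality variances (> 0 or Inf).
#' @return convex weight vector (nonnegative, sums to 1).
#' @export
#' @examples
#' inverseVarianceWeights(c(1, 4))        # (0.8, 0.2)
#' inverseVarianceWeights(c(1, Inf, Inf)) # (1, 0, 0)
inverseVarianceWeights <- function(sigma2) {
  if (!length(sigma2)) stop("'sigma2' must be nonempty")
  if (any(is.na(sigma2)) || any(sigma2 < 0))
    stop("variances must be nonnegative (or Inf for absent modalities)")
  finite <- is.finite(sigma2)
  if (!any(finite)) stop("all variances are infinite; no usable modality")
  w <- numeric(length(sigma2))
  names(w) <- names(sigma2)
  eps <- .Machine$double.eps
  zeros <- finite & sigma2 <= eps
  if (all(sigma2[finite] <= eps)) {
    w[finite] <- 1 / sum(finite)
  } else if (any(zeros)) {
    w[zeros] <- 1 / sum(zeros)
  } else {
    inv <- ifelse(finite, 1 / sigma2, 0)
    w <- inv / sum(inv)
  }
  w
}

#' Uncertainty-weighted fusion
#'
#' \eqn{Z_{fused} = \sum_i w_i Z_i} with inverse-variance (or any convex)
#' weights in place of attention weights; identical contract to
#' \code{\link{fuseEmbeddings}}.
#'
#' @param embeddings list of \linkS4class{ModalityEmbedding} or numeric
#'   vectors.
#' @param weights convex weight vector aligned with \code{embeddings}.
#' @return fused numeric vector.
#' @export
uncertaintyWeightedFuse <- function(embeddings, weights) {
  if (any(weights < -1e-9) || abs(sum(weights) - 1) > 1e-9)
    stop("'weights' must be convex (nonnegative, sum to 1)")
  fuseEmbeddings(embeddings, weights)
}

#' Entropy of an attention map / a predicted distribution
#'
#' Shannon entropy \eqn{-\sum p \log p} in nats (0 log 0 = 0), optionally
#' normalized by \eqn{\log(\mathrm{length})} so the uniform vector maps
#' to 1.
#'
#' @param alpha attention weight vector (valid probability vector).
#' @param yhat predicted class-probability vector.
#' @param normalized normalize to [0, 1]?
#' @return nonnegative scalar.
#' @name entropies
NULL

#' @rdname entropies
#' @export
attentionEntropy <- function(alpha, normalized = FALSE)
  shannonEntropy(alpha, normalized = normalized)

#' @rdname entropies
#' @export
predictionEntropy <- function(yhat, normalized = FALSE)
  shannonEntropy(yhat, normalized = normalized)

#' Entropy-matching calibration loss
#'
#' \deqn{L_{cal} = |H(\hat y) - A(\alpha)|,} encouraging the model to be
#' uncertain when its attention is diffuse and confident only when the
#' attention is sharply focused.  Because \eqn{H(\hat y)} lives in
#' \eqn{[0, \log K]} and \eqn{A(\alpha)} in \eqn{[0, \log M]} with
#' generally \eqn{K \neq M}, the default normalizes each entropy by its own
#' maximum, making the loss scale-consistent and bounded in [0, 1];
#' \code{normalized = FALSE} reproduces the raw difference.  Exact zeros in
#' \code{alpha} are treated as absent modalities: the attention entropy is
#' computed over the nonzero support.
#'
#' @param yhat predicted class-probability vector (length K).
#' @param alpha attention weights (zeros mark absent modalities).
#' @param normalized compare normalized entropies?
#' @return nonnegative scalar; 0 iff the two (normalized) entropies agree.
#' @export
#' @examples
#' calibrationLoss(rep(1 / 4, 4), rep(1 / 3, 3))  # both uniform: 0
#' calibrationLoss(c(0.5, 0.5), c(1, 0, 0))       # 1
calibrationLoss <- function(yhat, alpha, normalized = TRUE) {
  sup <- alpha[alpha > 0]
  if (!length(sup)) stop("'alpha' has empty support")
  h <- shannonEntropy(yhat, normalized = normalized)
  a <- shannonEntropy(sup / sum(sup), normalized = normalized)
  abs(h - a)
}

#' Predict with uncertainty-weighted or hybrid fusion
#'
#' Alternative inference-time fusion strategies: \code{"attention"} is the
#' trained softmax-attention pathway, \code{"inverse_variance"} replaces
#' the attention weights by inverse-variance weights estimated with
#' MC-dropout, and \code{"product"} multiplies the two weight vectors and
#' renormalizes.
#'
#' @param model a trained \linkS4class{OncoModel} (tailored encoders).
#' @param sample a \linkS4class{PatientSample}.
#' @param strategy fusion strategy.
#' @param T MC-dropout passes for the variance estimate.
#' @param seed RNG seed.
#' @return list with \code{probabilities}, \code{weights} (the convex
#'   fusion weights actually used), \code{alpha}, \code{sigma2} and
#'   \code{zFused}.
#' @export
predictWithStrategy <- function(model, sample,
                                strategy = c("attention",
                                             "inverse_variance", "product"),
                                T = 20L, seed = 1L) {
  strategy <- match.arg(strategy)
  fwd <- sampleForward(model@params, model@encoderConfig, model@inputSpec,
                       sample, stochastic = FALSE)
  if (strategy == "attention")
    return(list(probabilities = fwd$probs, weights = fwd$alpha,
                alpha = fwd$alpha, sigma2 = NULL, zFused = fwd$zf))
  sigma2 <- modalityVariance(model, sample, T = T, seed = seed)
  ivw <- inverseVarianceWeights(sigma2)
  w <- if (strategy == "inverse_variance") ivw else {
    pr <- fwd$alpha * ivw
    if (sum(pr) <= 0) ivw else pr / sum(pr)
  }
  pm <- MODALITIES[sample@modalityMask[MODALITIES]]
  zf <- numeric(model@encoderConfig$d)
  for (m in pm) zf <- zf + w[[m]] * fwd$z[[m]]
  cls <- classifyFused(zf, model)
  list(probabilities = cls$probabilities, weights = w, alpha = fwd$alpha,
       sigma2 = sigma2, zFused = zf)
}
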
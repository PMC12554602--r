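#' Adversarial domain-adaptation loss
#'
#' \deqn{L_{DA} = \mathrm{mean}\,\log d_s + \mathrm{mean}\,\log(1 - d_t)}
#' where \eqn{d_s} are discriminator probabilities on source-domain
#' features and \eqn{d_t} on target-domain features.  The discriminator
#' ascends this objective while the encoder descends it (alternating
#' updates).  Probabilities at exactly 0 or 1 are clipped to
#' \eqn{[10^{-7}, 1 - 10^{-7}]} with a warning.
#'
#' @param dSource,dTarget numeric vectors of discriminator probabilities.
#' @return scalar loss (nonpositive; 0 is the supremum).
#' @export
#' @examples
#' adversarialDALoss(0.5, 0.5)  # 2 * log(0.5)
adversarialDALoss <- function(dSource, dTarget) {
  if (!length(dSource) || !length(dTarget))
    stop("both domains need at least one probability")
  if (any(dSource < 0 | dSource > 1) || any(dTarget < 0 | dTarget > 1))
    stop("discriminator outputs must be probabilities in [0, 1]")
  clip <- function(p, nm) {
    if (any(p <= 0 | p >= 1)) {
      warning("clipping ", nm, " probabilities away from {0, 1}")
      p <- pmin(pmax(p, SIGMOID_EPS), 1 - SIGMOID_EPS)
    }
    p
  }
  dSource <- clip(dSource, "source")
  dTarget <- clip(dTarget, "target")
  mean(log(dSource)) + mean(log(1 - dTarget))
}

#' Kernel maximum mean discrepancy
#'
#' Biased squared-MMD estimate with a Gaussian kernel
#' \eqn{k(x, y) = \exp(-\|x - y\|^2 / (2\sigma^2))}:
#' \deqn{\widehat{\mathrm{MMD}}^2 = \overline{k(s, s)} +
#'   \overline{k(t, t)} - 2\,\overline{k(s, t)}.}
#' The default bandwidth is the median heuristic: the median of all
#' pairwise Euclidean distances across the pooled sample.
#'
#' @param Zs,Zt numeric matrices (rows are samples) or vectors (treated as
#'   single samples).
#' @param bandwidth Gaussian kernel bandwidth \eqn{\sigma > 0}; NULL for
#'   the median heuristic.
#' @return nonnegative scalar (up to numerical noise around 0).
#' @export
#' @examples
#' mmdDivergence(matrix(0, 1, 2), matrix(c(3, 4), 1, 2), bandwidth = 1)
mmdDivergence <- function(Zs, Zt, bandwidth = NULL) {
  toMat <- function(z) if (is.matrix(z)) z else matrix(z, nrow = 1L)
  Zs <- toMat(Zs); Zt <- toMat(Zt)
  if (nrow(Zs) == 0L || nrow(Zt) == 0L)
    stop("both sample sets must be nonempty")
  if (ncol(Zs) != ncol(Zt)) stop("sample dimensions differ")
  sq <- function(A, B) {
    an <- rowSums(A^2); bn <- rowSums(B^2)
    d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
    pmax(d2, 0)
  }
  if (is.null(bandwidth)) {
    pooled <- rbind(Zs, Zt)
    d2 <- sq(pooled, pooled)
    dist <- sqrt(d2[upper.tri(d2)])
    bandwidth <- stats::median(dist)
    if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 1
  }
  if (bandwidth <= 0) stop("'bandwidth' must be > 0")
  k <- function(d2) exp(-d2 / (2 * bandwidth^2))
  mean(k(sq(Zs, Zs))) + mean(k(sq(Zt, Zt))) - 2 * mean(k(sq(Zs, Zt)))
}

#' Cross-domain prediction consistency loss
#'
#' Mean squared Euclidean distance between paired source and target
#' predictions, \eqn{\mathrm{mean}_i \|f(x_s^i) - f(x_t^i)\|^2}.
#'
#' @param predSource,predTarget paired lists (or matrices, rows paired) of
#'   prediction vectors.
#' @return nonnegative scalar; 0 iff all pairs are identical.
#' @export
consistencyLoss <- function(predSource, predTarget) {
  toRows <- function(x) if (is.matrix(x)) asplit(x, 1L) else
    if (is.list(x)) x else list(x)
  ps <- toRows(predSource); pt <- toRows(predTarget)
  if (length(ps) != length(pt))
    stop("prediction lists must be paired (equal length)")
  if (!length(ps)) stop("need at least one pair")
  mean(vapply(seq_along(ps), function(i) {
    a <- as.numeric(ps[[i]]); b <- as.numeric(pt[[i]])
    if (length(a) != length(b)) stop("pair ", i, " has mismatched lengths")
    sum((a - b)^2)
  }, numeric(1)))
}

#' One alternating adversarial update
#'
#' Performs a single plain-gradient update of either the domain
#' discriminator (ascending the adversarial objective, encoders untouched)
#' or the encoder pathway (descending the classification loss plus the
#' weighted adversarial confusion term, discriminator untouched).  The
#' parameters of the component that is not being updated are returned
#' bit-for-bit unchanged.
#'
#' @param model an \linkS4class{OncoModel} whose parameters include a
#'   domain discriminator (train with \code{daWeight > 0} or build with
#'   such a \code{trainConfig}).
#' @param batch list of \linkS4class{PatientSample} containing both
#'   domains.
#' @param mode "discriminator_step" or "encoder_step".
#' @param lr learning rate of the plain gradient update.
#' @return the updated \linkS4class{OncoModel}.
#' @export
adversarialTrainingStep <- function(model, batch,
                                    mode = c("discriminator_step",
                                             "encoder_step"),
                                    lr = 0.01) {
  mode <- match.arg(mode)
  P <- model@params
  if (!length(discParamNames(P)))
    stop("model has no domain discriminator; build it with daWeight > 0")
  cfg <- model@encoderConfig
  spec <- model@inputSpec
  train <- model@trainConfig
  domains <- vapply(batch, function(s) s@domainId, character(1))
  srcI <- which(domains == "source"); tgtI <- which(domains == "target")
  if (!length(srcI) || !length(tgtI))
    stop("batch must contain both source and target samples")
  fwds <- lapply(batch, function(s)
    sampleForward(P, cfg, spec, s, stochastic = FALSE))
  dfw <- lapply(fwds, function(f) discForward(f$zf, P))

  discNames <- discParamNames(P)
  if (mode == "discriminator_step") {
    gD <- newGradEnv(P[discNames])
    for (i in srcI)
      discBackward((1 - dfw[[i]]$p) / length(srcI), dfw[[i]], P, gD)
    for (i in tgtI)
      discBackward(-dfw[[i]]$p / length(tgtI), dfw[[i]], P, gD)
    for (nm in discNames)            # ascend
      P[[nm]] <- P[[nm]] + lr * gD[[nm]]
  } else {
    encNames <- setdiff(names(P), discNames)
    g <- newGradEnv(P[encNames])
    labels <- vapply(batch, function(s) s@label, integer(1))
    nb <- length(batch)
    for (i in seq_len(nb)) {
      p <- fwds[[i]]$probs
      oh <- numeric(length(p)); oh[labels[i] + 1L] <- 1
      dlog <- (p - oh) / nb
      side <- if (i %in% srcI) (1 - dfw[[i]]$p) / length(srcI)
              else -dfw[[i]]$p / length(tgtI)
      dz <- train$daWeight * discBackward(side, dfw[[i]], P)
      sampleBackward(fwds[[i]], P, cfg, spec, g, dlog, dzfExtra = dz)
    }
    for (nm in encNames)             # descend
      P[[nm]] <- P[[nm]] - lr * g[[nm]]
  }
  if (any(!vapply(P, function(x) all(is.finite(x)), logical(1))))
    stop("adversarial update produced non-finite parameters")
  model@params <- P
  model
}

#' Fused embeddings of a cohort
#'
#' Deterministic fused representation \eqn{Z_{fused}} of every patient,
#' with the domain label of each row; the standard input to
#' \code{\link{mmdDivergence}} when diagnosing domain alignment.
#'
#' @param model an \linkS4class{OncoModel}.
#' @param cohort an \linkS4class{OncoCohort}.
#' @return list with matrix \code{Z} (patients x d) and character vector
#'   \code{domain}.
#' @export
fusedEmbeddings <- function(model, cohort) {
  samp <- cohort@samples
  Z <- matrix(0, length(samp), model@encoderConfig$d)
  for (i in seq_along(samp))
    Z[i, ] <- sampleForward(model@params, model@encoderConfig,
                            model@inputSpec, samp[[i]],
                            stochastic = FALSE)$zf
  list(Z = Z, domain = vapply(samp, function(s) s@domainId, character(1)))
}
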
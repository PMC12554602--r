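#' Training configuration
#'
#' Optimization and objective settings for \code{\link{trainFusionModel}}.
#' Optimizer defaults follow the conventions of large-scale training of
#' this architecture (Adam with \eqn{\beta_1 = 0.9}, \eqn{\beta_2 = 0.999},
#' initial learning rate 2e-4, cosine annealing, batch size 64); desk-scale
#' runs on small synthetic cohorts use a larger learning rate and smaller
#' batches, which every caller can set here.
#'
#' @param epochs number of passes over the training set.
#' @param batchSize minibatch size.
#' @param lr initial Adam learning rate.
#' @param beta1,beta2 Adam moment decays.
#' @param cosineAnneal decay the learning rate with a cosine schedule?
#' @param lambda L2 penalty weight on the attention vector w.
#' @param beta L2 (Frobenius) penalty weight on the classifier matrix.
#' @param weightDecay optional global L2 penalty on all parameters
#'   (the undifferentiated \eqn{\lambda\|\theta\|^2} variant; 0 disables).
#' @param modalityDropoutRate probability of masking each present modality
#'   per training sample (0 disables).
#' @param contrastiveWeight weight of the cross-modal triplet alignment
#'   loss (0 disables).
#' @param contrastiveMargin triplet margin \eqn{\tau}.
#' @param daWeight weight of the adversarial domain-adaptation term
#'   (0 disables; > 0 adds a domain discriminator).
#' @param daMode "alternating" discriminator/encoder updates, or "grl"
#'   (gradient-reversal style joint update).
#' @param daDiscSteps discriminator updates per encoder update; keeping the
#'   discriminator near-optimal prevents the degenerate "domain swap"
#'   response of the encoder to a stale discriminator.
#' @param daDiscLrMult learning-rate multiplier for the discriminator.
#' @param consistencyWeight weight of the source/target prediction
#'   consistency loss (0 disables).
#' @param calibrationWeight weight of the entropy-matching calibration
#'   loss (0 disables).
#' @param reconstructionWeight weight of the optional per-modality linear
#'   self-reconstruction heads (squared error against the raw modality
#'   content; 0 disables, the default).
#' @param epsClip cross-entropy probability floor.
#' @return a named list.
#' @export
trainConfig <- function(epochs = 10L, batchSize = 64L, lr = 2e-4,
                        beta1 = 0.9, beta2 = 0.999, cosineAnneal = TRUE,
                        lambda = 1e-4, beta = 1e-4, weightDecay = 0,
                        modalityDropoutRate = 0,
                        contrastiveWeight = 0.1, contrastiveMargin = 1,
                        daWeight = 0, daMode = c("alternating", "grl"),
                        daDiscSteps = 3L, daDiscLrMult = 5,
                        consistencyWeight = 0, calibrationWeight = 0.1,
                        reconstructionWeight = 0, epsClip = 1e-12) {
  if (modalityDropoutRate < 0 || modalityDropoutRate >= 1)
    stop("'modalityDropoutRate' must be in [0, 1)")
  stopifnot(lambda >= 0, beta >= 0, weightDecay >= 0, contrastiveWeight >= 0,
            daWeight >= 0, consistencyWeight >= 0, calibrationWeight >= 0,
            reconstructionWeight >= 0)
  list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
       lr = lr, beta1 = beta1, beta2 = beta2,
       cosineAnneal = isTRUE(cosineAnneal),
       lambda = lambda, beta = beta, weightDecay = weightDecay,
       modalityDropoutRate = modalityDropoutRate,
       contrastiveWeight = contrastiveWeight,
       contrastiveMargin = contrastiveMargin,
       daWeight = daWeight, daMode = match.arg(daMode),
       daDiscSteps = as.integer(daDiscSteps),
       daDiscLrMult = daDiscLrMult,
       consistencyWeight = consistencyWeight,
       calibrationWeight = calibrationWeight,
       reconstructionWeight = reconstructionWeight,
       epsClip = epsClip)
}

## ---- domain discriminator ----------------------------------------------

SIGMOID_EPS <- 1e-7

discForward <- function(z, P) {
  h <- pmax(as.numeric(P$disc_W_1 %*% z) + P$disc_b_1, 0)
  o <- sum(P$disc_W_2 * h) + P$disc_b_2[1L]
  p <- 1 / (1 + exp(-o))
  p <- min(max(p, SIGMOID_EPS), 1 - SIGMOID_EPS)
  list(p = p, h = h, o = o, z = z)
}

## Backward of d(loss)/d(o) through the discriminator; accumulates disc
## parameter grads into `g` (if not NULL) and returns d(loss)/dz.
discBackward <- function(dout, fw, P, g = NULL) {
  if (!is.null(g)) {
    addGrad(g, "disc_W_2", matrix(dout * fw$h, 1L))
    addGrad(g, "disc_b_2", dout)
  }
  dh <- as.numeric(P$disc_W_2) * dout
  dh <- dh * (fw$h > 0)
  if (!is.null(g)) {
    addGrad(g, "disc_W_1", dh %o% fw$z)
    addGrad(g, "disc_b_1", dh)
  }
  as.numeric(t(P$disc_W_1) %*% dh)
}

## ---- calibration-loss gradient seeds -----------------------------------

## Returns list(loss, dlogits, dAlpha) for one sample, or NULL when the
## gradient is undefined (entropies exactly equal).
calibrationSeeds <- function(probs, logits, alpha, present) {
  K <- length(probs)
  pm <- names(alpha)[alpha > 0]
  M <- length(pm)
  Hn <- shannonEntropy(probs, normalized = TRUE)
  An <- if (M > 1L) shannonEntropy(alpha[pm] / sum(alpha[pm]),
                                   normalized = TRUE) else 0
  loss <- abs(Hn - An)
  s <- sign(Hn - An)
  dlogits <- numeric(K)
  dAlpha <- stats::setNames(numeric(length(alpha)), names(alpha))
  if (s != 0) {
    if (K > 1L) {
      dH <- -(log(pmax(probs, 1e-300)) + 1) / log(K)
      dp <- s * dH
      dlogits <- probs * (dp - sum(probs * dp))
    }
    if (M > 1L) {
      a <- alpha[pm]
      dA <- -(log(pmax(a, 1e-300)) + 1) / log(M)
      dAlpha[pm] <- -s * dA
    }
  }
  list(loss = loss, dlogits = dlogits, dAlpha = dAlpha)
}

## ---- end-to-end training ------------------------------------------------

#' Train the multimodal fusion model end to end
#'
#' Joint gradient training of the modality encoders, the attention fusion
#' pathway and the classifier head on the regularized cross-entropy
#' objective, with optional contrastive cross-modal alignment, adversarial
#' domain adaptation (alternating discriminator/encoder updates),
#' source/target consistency and the entropy-matching calibration term.
#' Deterministic given \code{seed}.
#'
#' @param cohort an \linkS4class{OncoCohort} (the training split).
#' @param encoder an \code{\link{encoderConfig}}.
#' @param train a \code{\link{trainConfig}}.
#' @param seed RNG seed covering initialization, shuffling, dropout and
#'   modality dropout.
#' @param model optionally a pre-built \linkS4class{OncoModel} to continue
#'   training (its configs override \code{encoder}/\code{train}).
#' @return a trained \linkS4class{OncoModel}; \code{trainingLog()} returns
#'   one row per epoch with the loss components and training accuracy.
#' @export
trainFusionModel <- function(cohort, encoder = encoderConfig(),
                             train = trainConfig(), seed = 1L,
                             model = NULL) {
  stopifnot(is(cohort, "OncoCohort"))
  samp <- cohort@samples
  n <- length(samp)
  if (n < 1L) stop("cannot train on an empty cohort")
  spec <- inputSpec(cohort@config)
  if (!is.null(model)) {
    encoder <- model@encoderConfig
    train <- model@trainConfig
    P <- model@params
    set.seed(deriveSeed(seed, 1L))
  } else {
    P <- initParams(encoder, spec, deriveSeed(seed, 1L),
                    withDiscriminator = train$daWeight > 0,
                    withReconstruction = (train$reconstructionWeight %||% 0) > 0)
  }
  set.seed(deriveSeed(seed, 2L))

  discNames <- discParamNames(P)
  encNames <- setdiff(names(P), discNames)
  adamEnc <- adamInit(P[encNames])
  adamDisc <- if (length(discNames)) adamInit(P[discNames]) else NULL

  bs <- min(train$batchSize, n)
  stepsPerEpoch <- ceiling(n / bs)
  totalSteps <- max(1L, train$epochs * stepsPerEpoch)
  step <- 0L
  logRows <- vector("list", train$epochs)

  for (epoch in seq_len(train$epochs)) {
    ord <- sample.int(n)
    epochLoss <- c(total = 0, ce = 0, contrastive = 0, da = 0,
                   consistency = 0, calibration = 0, reconstruction = 0)
    epochCorrect <- 0L
    for (b in seq_len(stepsPerEpoch)) {
      idx <- ord[((b - 1L) * bs + 1L):min(b * bs, n)]
      batch <- samp[idx]
      nb <- length(batch)
      step <- step + 1L
      lr <- if (train$cosineAnneal)
        train$lr * 0.5 * (1 + cos(pi * (step - 1L) / totalSteps))
      else train$lr

      ## forwards (with modality dropout and unit dropout active)
      fwds <- vector("list", nb)
      for (i in seq_len(nb)) {
        pres <- batch[[i]]@modalityMask
        if (train$modalityDropoutRate > 0 && encoder$style == "tailored")
          pres <- stats::setNames(
            dropPresentMask(pres, train$modalityDropoutRate), MODALITIES)
        fwds[[i]] <- sampleForward(P, encoder, spec, batch[[i]],
                                   stochastic = TRUE, present = pres)
      }
      labels <- vapply(batch, function(s) s@label, integer(1))
      probsM <- do.call(rbind, lapply(fwds, `[[`, "probs"))
      epochCorrect <- epochCorrect +
        sum(max.col(probsM, ties.method = "first") - 1L == labels)
      ce <- mean(-log(pmax(probsM[cbind(seq_len(nb), labels + 1L)],
                           train$epsClip)))

      ## gradient seeds per sample
      dlogits <- lapply(seq_len(nb), function(i) {
        p <- fwds[[i]]$probs
        oh <- numeric(length(p)); oh[labels[i] + 1L] <- 1
        (p - oh) / nb
      })
      dzfExtra <- vector("list", nb)
      dAlphaExtra <- vector("list", nb)
      dZextra <- lapply(seq_len(nb), function(i) list())

      ## calibration
      calLoss <- 0
      if (train$calibrationWeight > 0) {
        for (i in seq_len(nb)) {
          cs <- calibrationSeeds(fwds[[i]]$probs, fwds[[i]]$logits,
                                 fwds[[i]]$alpha, fwds[[i]]$present)
          calLoss <- calLoss + cs$loss / nb
          dlogits[[i]] <- dlogits[[i]] +
            train$calibrationWeight * cs$dlogits / nb
          dAlphaExtra[[i]] <- train$calibrationWeight * cs$dAlpha / nb
        }
      }

      ## contrastive cross-modal alignment (tailored encoders only)
      conLoss <- 0
      if (train$contrastiveWeight > 0 && encoder$style == "tailored") {
        triplets <- list()
        for (i in seq_len(nb)) {
          pm <- MODALITIES[fwds[[i]]$present[MODALITIES]]
          if (length(pm) < 2L) next
          negCand <- which(labels != labels[i] &
                             vapply(fwds, function(f)
                               isTRUE(f$present[[pm[1L]]]), logical(1)))
          if (!length(negCand)) next
          j <- negCand[sample.int(length(negCand), 1L)]
          triplets[[length(triplets) + 1L]] <-
            list(i = i, j = j, am = pm[1L], pm2 = pm[2L])
        }
        if (length(triplets)) {
          for (tr in triplets) {
            a <- fwds[[tr$i]]$z[[tr$am]]
            p <- fwds[[tr$i]]$z[[tr$pm2]]
            nn <- fwds[[tr$j]]$z[[tr$am]]
            l <- train$contrastiveMargin + sum((a - p)^2) - sum((a - nn)^2)
            if (l > 0) {
              conLoss <- conLoss + l / length(triplets)
              cw <- train$contrastiveWeight / length(triplets)
              dZextra[[tr$i]][[tr$am]] <-
                (dZextra[[tr$i]][[tr$am]] %||% 0) + cw * 2 * (nn - p)
              dZextra[[tr$i]][[tr$pm2]] <-
                (dZextra[[tr$i]][[tr$pm2]] %||% 0) + cw * 2 * (p - a)
              dZextra[[tr$j]][[tr$am]] <-
                (dZextra[[tr$j]][[tr$am]] %||% 0) + cw * 2 * (a - nn)
            }
          }
        }
      }

      ## consistency between paired source/target predictions
      consLoss <- 0
      if (train$consistencyWeight > 0) {
        srcI <- which(vapply(batch, function(s) s@domainId == "source",
                             logical(1)))
        tgtI <- which(vapply(batch, function(s) s@domainId == "target",
                             logical(1)))
        pairs <- pairByLabel(labels, srcI, tgtI)
        if (nrow(pairs)) {
          for (r in seq_len(nrow(pairs))) {
            ps <- fwds[[pairs$s[r]]]$probs
            pt <- fwds[[pairs$t[r]]]$probs
            consLoss <- consLoss + sum((ps - pt)^2) / nrow(pairs)
            cwt <- train$consistencyWeight / nrow(pairs)
            dps <- cwt * 2 * (ps - pt)
            dpt <- -dps
            dlogits[[pairs$s[r]]] <- dlogits[[pairs$s[r]]] +
              ps * (dps - sum(ps * dps))
            dlogits[[pairs$t[r]]] <- dlogits[[pairs$t[r]]] +
              pt * (dpt - sum(pt * dpt))
          }
        }
      }

      ## adversarial domain adaptation
      daLoss <- 0
      if (train$daWeight > 0) {
        domains <- vapply(batch, function(s) s@domainId, character(1))
        srcI <- which(domains == "source"); tgtI <- which(domains == "target")
        if (length(srcI) && length(tgtI)) {
          ## discriminator ascent steps on current (detached) fused vectors
          nDiscSteps <- if (train$daMode == "alternating")
            max(1L, train$daDiscSteps) else 1L
          for (ds in seq_len(nDiscSteps)) {
            gD <- newGradEnv(P[discNames])
            dfw <- lapply(fwds, function(f) discForward(f$zf, P))
            for (i in srcI)
              discBackward((1 - dfw[[i]]$p) / length(srcI), dfw[[i]], P, gD)
            for (i in tgtI)
              discBackward(-dfw[[i]]$p / length(tgtI), dfw[[i]], P, gD)
            ## Adam minimizes, so ascend by feeding the negated gradient
            upd <- adamStep(P[discNames],
                            gradAsList(gD, P[discNames], scale = -1),
                            adamDisc, lr * train$daDiscLrMult)
            P[discNames] <- upd$params
            adamDisc <- upd$state
          }
          ## encoder confusion term (through the updated discriminator for
          ## alternating mode; "grl" reuses the pre-update pass)
          if (train$daMode == "alternating")
            dfw <- lapply(fwds, function(f) discForward(f$zf, P))
          pS <- vapply(dfw[srcI], `[[`, numeric(1), "p")
          pT <- vapply(dfw[tgtI], `[[`, numeric(1), "p")
          daLoss <- mean(log(pS)) + mean(log(1 - pT))
          for (i in srcI) {
            dz <- discBackward((1 - dfw[[i]]$p) / length(srcI), dfw[[i]], P)
            dzfExtra[[i]] <- (dzfExtra[[i]] %||% 0) + train$daWeight * dz
          }
          for (i in tgtI) {
            dz <- discBackward(-dfw[[i]]$p / length(tgtI), dfw[[i]], P)
            dzfExtra[[i]] <- (dzfExtra[[i]] %||% 0) + train$daWeight * dz
          }
        }
      }

      ## backward over the batch
      g <- newGradEnv(P[encNames])

      ## optional self-reconstruction heads (tailored encoders only)
      recLoss <- 0
      rw <- train$reconstructionWeight %||% 0
      if (rw > 0 && encoder$style == "tailored") {
        for (i in seq_len(nb)) {
          pm <- MODALITIES[fwds[[i]]$present[MODALITIES]]
          for (m in pm) {
            tgt <- reconTarget(batch[[i]], m, spec)
            Wr <- P[[paste0("rec_W_", m)]]
            err <- as.numeric(Wr %*% fwds[[i]]$z[[m]]) +
              P[[paste0("rec_b_", m)]] - tgt
            recLoss <- recLoss + mean(err^2) / nb
            derr <- rw * 2 * err / (length(err) * nb)
            addGrad(g, paste0("rec_W_", m), derr %o% fwds[[i]]$z[[m]])
            addGrad(g, paste0("rec_b_", m), derr)
            dZextra[[i]][[m]] <- (dZextra[[i]][[m]] %||% 0) +
              as.numeric(t(Wr) %*% derr)
          }
        }
      }

      for (i in seq_len(nb))
        sampleBackward(fwds[[i]], P, encoder, spec, g, dlogits[[i]],
                       dzfExtra = dzfExtra[[i]],
                       dAlphaExtra = dAlphaExtra[[i]],
                       dZextra = dZextra[[i]])
      ## structured regularization (once per batch, mean reduction)
      addGrad(g, "fus_w", 2 * train$lambda * P$fus_w)
      addGrad(g, "out_W", 2 * train$beta * P$out_W)
      grads <- gradAsList(g, P[encNames])
      if (train$weightDecay > 0)
        for (nm in encNames)
          grads[[nm]] <- grads[[nm]] + 2 * train$weightDecay * P[[nm]]

      total <- ce + train$lambda * sum(P$fus_w^2) +
        train$beta * sum(P$out_W^2) +
        train$contrastiveWeight * conLoss +
        train$daWeight * daLoss +
        train$consistencyWeight * consLoss +
        train$calibrationWeight * calLoss +
        rw * recLoss
      if (!is.finite(total))
        stop("training diverged at epoch ", epoch, ", step ", b,
             " (non-finite loss)")

      upd <- adamStep(P[encNames], grads, adamEnc, lr)
      P[encNames] <- upd$params
      adamEnc <- upd$state

      epochLoss <- epochLoss +
        c(total = total, ce = ce, contrastive = conLoss, da = daLoss,
          consistency = consLoss, calibration = calLoss,
          reconstruction = recLoss) / stepsPerEpoch
    }
    logRows[[epoch]] <- data.frame(
      epoch = epoch, loss = epochLoss[["total"]], ce = epochLoss[["ce"]],
      contrastive = epochLoss[["contrastive"]], da = epochLoss[["da"]],
      consistency = epochLoss[["consistency"]],
      calibration = epochLoss[["calibration"]],
      reconstruction = epochLoss[["reconstruction"]],
      trainAccuracy = epochCorrect / n)
  }
  new("OncoModel", params = P, encoderConfig = encoder, trainConfig = train,
      inputSpec = spec, log = do.call(rbind, logRows), trained = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Pair source and target batch members with matching labels (seeded by the
## ambient RNG stream); returns a data.frame with columns s, t.
pairByLabel <- function(labels, srcI, tgtI) {
  ss <- integer(); tt <- integer()
  for (lab in unique(labels[tgtI])) {
    sl <- srcI[labels[srcI] == lab]
    tl <- tgtI[labels[tgtI] == lab]
    if (!length(sl)) next
    for (t in tl) {
      ss <- c(ss, sl[sample.int(length(sl), 1L)])
      tt <- c(tt, t)
    }
  }
  data.frame(s = ss, t = tt)
}
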
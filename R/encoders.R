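#' Encoder architecture configuration
#'
#' Describes the three modality-specific encoders that project each input
#' stream into the shared d-dimensional latent space: a strided
#' convolutional network with global average pooling for images, a
#' multi-head self-attention encoder with sinusoidal positional encoding
#' for genomic token sequences, and a multilayer perceptron for clinical
#' covariates.
#'
#' @param d shared embedding dimension.
#' @param imageChannels output channels of each convolution layer.
#' @param imageKernel square kernel size.
#' @param imageStride stride (downsampling factor) of each convolution.
#' @param genomicEmbDim token embedding size.
#' @param genomicHeads number of attention heads.
#' @param genomicLayers number of self-attention layers.
#' @param genomicDk per-head key/query dimension.
#' @param genomicPosEncoding add sinusoidal positional encodings?
#' @param genomicPooling "mean" (average over tokens) or "first".
#' @param clinicalHidden hidden-layer widths of the clinical MLP
#'   (\code{integer(0)} gives a single linear projection).
#' @param activation "relu", "gelu" or "identity".
#' @param dropout dropout rate in [0, 1) applied to clinical hidden layers
#'   and to every modality embedding (the Monte-Carlo-dropout sites).
#' @param style "tailored" for the three modality-specific encoders, or
#'   "shared" for the flattened-input shared-MLP baseline used by the
#'   encoder ablation.
#' @param sharedHidden hidden widths of the shared-MLP baseline.
#' @param fusion "attention" for learned softmax attention over modalities,
#'   or "uniform" for the unweighted mean used by the fusion ablation.
#' @return a named list.
#' @export
encoderConfig <- function(d = 32L,
                          imageChannels = c(4L, 8L),
                          imageKernel = 3L,
                          imageStride = 2L,
                          genomicEmbDim = 16L,
                          genomicHeads = 2L,
                          genomicLayers = 2L,
                          genomicDk = 8L,
                          genomicPosEncoding = TRUE,
                          genomicPooling = c("mean", "first"),
                          clinicalHidden = c(16L),
                          activation = c("relu", "gelu", "identity"),
                          dropout = 0.1,
                          style = c("tailored", "shared"),
                          sharedHidden = c(32L),
                          fusion = c("attention", "uniform")) {
  if (dropout < 0 || dropout >= 1) stop("'dropout' must be in [0, 1)")
  if (d < 1L) stop("'d' must be >= 1")
  if (genomicDk < 1L) stop("'genomicDk' must be >= 1")
  list(d = as.integer(d),
       image = list(channels = as.integer(imageChannels),
                    kernel = as.integer(imageKernel),
                    stride = as.integer(imageStride)),
       genomic = list(embDim = as.integer(genomicEmbDim),
                      nHeads = as.integer(genomicHeads),
                      nLayers = as.integer(genomicLayers),
                      dK = as.integer(genomicDk),
                      posEncoding = isTRUE(genomicPosEncoding),
                      pooling = match.arg(genomicPooling)),
       clinical = list(hidden = as.integer(clinicalHidden)),
       activation = match.arg(activation),
       dropout = dropout,
       style = match.arg(style),
       shared = list(hidden = as.integer(sharedHidden)),
       fusion = match.arg(fusion))
}

## Input dimensions the model is built for, taken from a cohort config.
inputSpec <- function(config) {
  list(imageShape = config@imageShape,
       genomicLength = config@genomicLength,
       vocabSize = config@vocabSize,
       clinicalDim = config@clinicalDim,
       nClasses = config@nClasses)
}

## ---- parameter initialization ------------------------------------------

initParams <- function(cfg, spec, seed, withDiscriminator = FALSE,
                       discWidth = 32L, withReconstruction = FALSE) {
  set.seed(seed)
  P <- list()
  d <- cfg$d
  K <- spec$nClasses
  if (cfg$style == "tailored") {
    ## image CNN
    h <- spec$imageShape[1L]; w <- spec$imageShape[2L]
    cin <- spec$imageShape[3L]
    for (l in seq_along(cfg$image$channels)) {
      cout <- cfg$image$channels[l]
      kk <- cfg$image$kernel
      P[[paste0("img_convW_", l)]] <- glorot(kk * kk * cin, cout)
      P[[paste0("img_convb_", l)]] <- numeric(cout)
      h <- floor((h - kk) / cfg$image$stride) + 1L
      w <- floor((w - kk) / cfg$image$stride) + 1L
      if (h < 1L || w < 1L)
        stop("image encoder: layer ", l, " output collapses below 1x1")
      cin <- cout
    }
    P$img_projW <- glorot(d, cin)
    P$img_projb <- numeric(d)
    ## genomic transformer
    e <- cfg$genomic$embDim
    dk <- cfg$genomic$dK
    P$gen_embed <- glorot(spec$vocabSize, e)
    for (l in seq_len(cfg$genomic$nLayers)) {
      for (hh in seq_len(cfg$genomic$nHeads)) {
        P[[paste0("gen_Wq_", l, "_", hh)]] <- glorot(e, dk)
        P[[paste0("gen_Wk_", l, "_", hh)]] <- glorot(e, dk)
        P[[paste0("gen_Wv_", l, "_", hh)]] <- glorot(e, dk)
      }
      P[[paste0("gen_Wo_", l)]] <- glorot(cfg$genomic$nHeads * dk, e)
    }
    P$gen_projW <- glorot(d, e)
    P$gen_projb <- numeric(d)
    ## clinical MLP
    dims <- c(spec$clinicalDim, cfg$clinical$hidden, d)
    for (l in seq_len(length(dims) - 1L)) {
      P[[paste0("clin_W_", l)]] <- glorot(dims[l + 1L], dims[l])
      P[[paste0("clin_b_", l)]] <- numeric(dims[l + 1L])
    }
  } else {
    din <- prod(spec$imageShape) + spec$genomicLength + spec$clinicalDim
    dims <- c(din, cfg$shared$hidden, d)
    for (l in seq_len(length(dims) - 1L)) {
      P[[paste0("sh_W_", l)]] <- glorot(dims[l + 1L], dims[l])
      P[[paste0("sh_b_", l)]] <- numeric(dims[l + 1L])
    }
  }
  ## fusion attention vector and classifier head
  P$fus_w <- stats::rnorm(d, sd = 1 / sqrt(d))
  P$out_W <- glorot(K, d)
  P$out_b <- numeric(K)
  if (withDiscriminator) {
    P$disc_W_1 <- glorot(discWidth, d)
    P$disc_b_1 <- numeric(discWidth)
    P$disc_W_2 <- glorot(1L, discWidth)
    P$disc_b_2 <- numeric(1L)
  }
  ## optional per-modality linear self-reconstruction heads
  if (withReconstruction && cfg$style == "tailored") {
    for (m in MODALITIES) {
      len <- switch(m, image = prod(spec$imageShape),
                    genomic = spec$genomicLength,
                    clinical = spec$clinicalDim)
      P[[paste0("rec_W_", m)]] <- glorot(len, d)
      P[[paste0("rec_b_", m)]] <- numeric(len)
    }
  }
  P
}

## Raw reconstruction target of one modality (tokens rescaled to [0, 1]).
reconTarget <- function(sample, m, spec) {
  switch(m,
    image = as.numeric(sample@image),
    genomic = sample@genomic / max(1L, spec$vocabSize - 1L),
    clinical = sample@clinical)
}

## Parameter names belonging to the domain discriminator (updated only in
## discriminator steps) vs everything else (updated only in encoder steps).
discParamNames <- function(params) grep("^disc_", names(params), value = TRUE)

#' Construct an (untrained) multimodal fusion model
#'
#' @param config a \linkS4class{CohortConfig} describing the input
#'   dimensions the model is built for.
#' @param encoder an \code{\link{encoderConfig}} list.
#' @param train a \code{\link{trainConfig}} list.
#' @param seed RNG seed for parameter initialization.
#' @return an \linkS4class{OncoModel}.
#' @export
#' @examples
#' m <- oncoModel(cohortConfig(nPatients = 10), seed = 1)
#' m
oncoModel <- function(config, encoder = encoderConfig(),
                      train = trainConfig(), seed = 1L) {
  spec <- inputSpec(config)
  params <- initParams(
    encoder, spec, seed,
    withDiscriminator = train$daWeight > 0,
    withReconstruction = (train$reconstructionWeight %||% 0) > 0)
  new("OncoModel", params = params, encoderConfig = encoder,
      trainConfig = train, inputSpec = spec,
      log = data.frame(), trained = FALSE)
}

## ---- image encoder ------------------------------------------------------

imgForward <- function(x, P, cfg, spec) {
  if (!identical(dim(x), spec$imageShape))
    stop("image shape (", paste(dim(x), collapse = "x"),
         ") does not match expected (",
         paste(spec$imageShape, collapse = "x"), ")")
  if (any(!is.finite(x))) stop("image contains non-finite values")
  h <- spec$imageShape[1L]; w <- spec$imageShape[2L]
  cin <- spec$imageShape[3L]
  xv <- as.numeric(x)
  layers <- list()
  for (l in seq_along(cfg$image$channels)) {
    ii <- im2colIndex(h, w, cin, cfg$image$kernel, cfg$image$stride)
    Pm <- matrix(xv[ii$idx], nrow(ii$idx), ncol(ii$idx))
    pre <- sweep(Pm %*% P[[paste0("img_convW_", l)]], 2L,
                 P[[paste0("img_convb_", l)]], "+")
    out <- actFun(pre, cfg$activation)
    layers[[l]] <- list(idx = ii, patches = Pm, pre = pre,
                        inLen = length(xv), inDims = c(h, w, cin))
    h <- ii$outH; w <- ii$outW; cin <- cfg$image$channels[l]
    xv <- as.numeric(out)
  }
  lastOut <- matrix(xv, h * w, cin)
  pooled <- colMeans(lastOut)
  z <- as.numeric(P$img_projW %*% pooled) + P$img_projb
  list(z = z, pooled = pooled, np = h * w, layers = layers)
}

imgBackward <- function(dz, fw, P, cfg, g, inputGrad = FALSE) {
  addGrad(g, "img_projW", dz %o% fw$pooled)
  addGrad(g, "img_projb", dz)
  dpooled <- as.numeric(t(P$img_projW) %*% dz)
  dout <- matrix(rep(dpooled / fw$np, each = fw$np), fw$np,
                 length(dpooled))
  for (l in rev(seq_along(fw$layers))) {
    lay <- fw$layers[[l]]
    dpre <- dout * matrix(actGrad(lay$pre, cfg$activation), nrow(lay$pre))
    addGrad(g, paste0("img_convW_", l), t(lay$patches) %*% dpre)
    addGrad(g, paste0("img_convb_", l), colSums(dpre))
    if (l > 1L || inputGrad) {
      dP <- dpre %*% t(P[[paste0("img_convW_", l)]])
      dx <- numeric(lay$inLen)
      idx <- lay$idx$idx
      for (j in seq_len(nrow(idx)))
        dx[idx[j, ]] <- dx[idx[j, ]] + dP[j, ]
      dout <- matrix(dx, lay$inDims[1L] * lay$inDims[2L], lay$inDims[3L])
    }
  }
  if (inputGrad) as.numeric(dout) else invisible(NULL)
}

## ---- scaled dot-product attention --------------------------------------

#' Scaled dot-product attention
#'
#' Computes \eqn{\mathrm{softmax}(QK^\top/\sqrt{d_k})\,V} with a row-wise
#' softmax, so that every output row is a convex combination of the rows of
#' \code{V}.
#'
#' @param Q,K,V numeric matrices with matching shapes (tokens x dim for Q
#'   and K, tokens x value-dim for V).
#' @param dK positive scaling dimension (defaults to \code{ncol(K)}).
#' @return matrix of attended values, rows aligned with \code{Q}.
#' @export
#' @examples
#' Q <- matrix(0, 3, 2); K <- matrix(0, 3, 2); V <- diag(3)
#' scaledDotAttention(Q, K, V)  # uniform attention: column means of V
scaledDotAttention <- function(Q, K, V, dK = ncol(K)) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) stop("Q and K must have the same column count")
  if (nrow(K) != nrow(V)) stop("K and V must have the same row count")
  if (dK <= 0) stop("'dK' must be > 0")
  if (any(!is.finite(Q)) || any(!is.finite(K)) || any(!is.finite(V)))
    stop("attention inputs must be finite")
  S <- Q %*% t(K) / sqrt(dK)
  A <- softmaxRows(S)
  A %*% V
}

## ---- genomic encoder ----------------------------------------------------

genForward <- function(tok, P, cfg, spec) {
  m <- length(tok)
  if (any(tok < 0L | tok >= spec$vocabSize)) {
    bad <- which(tok < 0L | tok >= spec$vocabSize)[1L]
    stop("genomic token out of vocabulary at position ", bad,
         " (token ", tok[bad], ", vocab size ", spec$vocabSize, ")")
  }
  e <- cfg$genomic$embDim
  dk <- cfg$genomic$dK
  X <- P$gen_embed[tok + 1L, , drop = FALSE]
  if (cfg$genomic$posEncoding) X <- X + posEncoding(m, e)
  X0 <- X
  layers <- vector("list", cfg$genomic$nLayers)
  for (l in seq_len(cfg$genomic$nLayers)) {
    heads <- vector("list", cfg$genomic$nHeads)
    Hcat <- matrix(0, m, cfg$genomic$nHeads * dk)
    for (hh in seq_len(cfg$genomic$nHeads)) {
      Wq <- P[[paste0("gen_Wq_", l, "_", hh)]]
      Wk <- P[[paste0("gen_Wk_", l, "_", hh)]]
      Wv <- P[[paste0("gen_Wv_", l, "_", hh)]]
      Qm <- X %*% Wq; Km <- X %*% Wk; Vm <- X %*% Wv
      S <- Qm %*% t(Km) / sqrt(dk)
      A <- softmaxRows(S)
      Hh <- A %*% Vm
      heads[[hh]] <- list(Q = Qm, K = Km, V = Vm, A = A)
      Hcat[, (hh - 1L) * dk + seq_len(dk)] <- Hh
    }
    O <- Hcat %*% P[[paste0("gen_Wo_", l)]]
    layers[[l]] <- list(X = X, heads = heads, Hcat = Hcat)
    X <- X + O
  }
  pooled <- if (cfg$genomic$pooling == "mean") colMeans(X) else X[1L, ]
  z <- as.numeric(P$gen_projW %*% pooled) + P$gen_projb
  list(z = z, pooled = pooled, X = X, X0 = X0, layers = layers, tok = tok,
       m = m)
}

genBackward <- function(dz, fw, P, cfg, g, inputGrad = FALSE) {
  dk <- cfg$genomic$dK
  m <- fw$m
  addGrad(g, "gen_projW", dz %o% fw$pooled)
  addGrad(g, "gen_projb", dz)
  dpooled <- as.numeric(t(P$gen_projW) %*% dz)
  dX <- matrix(0, m, length(dpooled))
  if (cfg$genomic$pooling == "mean") {
    dX <- matrix(rep(dpooled / m, each = m), m, length(dpooled))
  } else {
    dX[1L, ] <- dpooled
  }
  for (l in rev(seq_len(cfg$genomic$nLayers))) {
    lay <- fw$layers[[l]]
    dO <- dX               # residual: dX flows to both X and O
    Wo <- P[[paste0("gen_Wo_", l)]]
    addGrad(g, paste0("gen_Wo_", l), t(lay$Hcat) %*% dO)
    dHcat <- dO %*% t(Wo)
    dXin <- dX             # residual path
    for (hh in seq_len(cfg$genomic$nHeads)) {
      hd <- lay$heads[[hh]]
      dHh <- dHcat[, (hh - 1L) * dk + seq_len(dk), drop = FALSE]
      dA <- dHh %*% t(hd$V)
      dV <- t(hd$A) %*% dHh
      dS <- hd$A * (dA - rowSums(dA * hd$A))
      dQ <- dS %*% hd$K / sqrt(dk)
      dK <- t(dS) %*% hd$Q / sqrt(dk)
      Wq <- P[[paste0("gen_Wq_", l, "_", hh)]]
      Wk <- P[[paste0("gen_Wk_", l, "_", hh)]]
      Wv <- P[[paste0("gen_Wv_", l, "_", hh)]]
      addGrad(g, paste0("gen_Wq_", l, "_", hh), t(lay$X) %*% dQ)
      addGrad(g, paste0("gen_Wk_", l, "_", hh), t(lay$X) %*% dK)
      addGrad(g, paste0("gen_Wv_", l, "_", hh), t(lay$X) %*% dV)
      dXin <- dXin + dQ %*% t(Wq) + dK %*% t(Wk) + dV %*% t(Wv)
    }
    dX <- dXin
  }
  ## embedding rows
  gEmb <- g$gen_embed
  for (i in seq_len(m)) {
    r <- fw$tok[i] + 1L
    gEmb[r, ] <- gEmb[r, ] + dX[i, ]
  }
  g$gen_embed <- gEmb
  if (inputGrad) dX else invisible(NULL)
}

## ---- clinical encoder ---------------------------------------------------

clinForward <- function(cvec, P, cfg, spec, stochastic = FALSE) {
  if (length(cvec) != spec$clinicalDim)
    stop("clinical vector has length ", length(cvec), ", expected ",
         spec$clinicalDim)
  if (any(!is.finite(cvec))) stop("clinical vector must be finite")
  nH <- length(cfg$clinical$hidden)
  a <- cvec
  caches <- vector("list", nH)
  for (l in seq_len(nH)) {
    pre <- as.numeric(P[[paste0("clin_W_", l)]] %*% a) +
      P[[paste0("clin_b_", l)]]
    act <- actFun(pre, cfg$activation)
    mask <- dropMask(length(act), cfg$dropout, stochastic)
    caches[[l]] <- list(input = a, pre = pre, mask = mask)
    a <- act * mask
  }
  lf <- nH + 1L
  z <- as.numeric(P[[paste0("clin_W_", lf)]] %*% a) +
    P[[paste0("clin_b_", lf)]]
  list(z = z, lastInput = a, caches = caches)
}

clinBackward <- function(dz, fw, P, cfg, g, inputGrad = FALSE) {
  nH <- length(fw$caches)
  lf <- nH + 1L
  addGrad(g, paste0("clin_W_", lf), dz %o% fw$lastInput)
  addGrad(g, paste0("clin_b_", lf), dz)
  da <- as.numeric(t(P[[paste0("clin_W_", lf)]]) %*% dz)
  for (l in rev(seq_len(nH))) {
    cc <- fw$caches[[l]]
    dpre <- da * cc$mask * actGrad(cc$pre, cfg$activation)
    addGrad(g, paste0("clin_W_", l), dpre %o% cc$input)
    addGrad(g, paste0("clin_b_", l), dpre)
    da <- as.numeric(t(P[[paste0("clin_W_", l)]]) %*% dpre)
  }
  if (inputGrad) da else invisible(NULL)
}

## ---- shared flattened-input baseline encoder ---------------------------

sharedFlatten <- function(sample, spec) {
  img <- if (sample@modalityMask[["image"]]) as.numeric(sample@image)
         else numeric(prod(spec$imageShape))
  gen <- if (sample@modalityMask[["genomic"]])
           sample@genomic / max(1L, spec$vocabSize - 1L)
         else numeric(spec$genomicLength)
  clin <- if (sample@modalityMask[["clinical"]]) sample@clinical
          else numeric(spec$clinicalDim)
  c(img, gen, clin)
}

sharedForward <- function(xflat, P, cfg, stochastic = FALSE) {
  nH <- length(cfg$shared$hidden)
  a <- xflat
  caches <- vector("list", nH)
  for (l in seq_len(nH)) {
    pre <- as.numeric(P[[paste0("sh_W_", l)]] %*% a) +
      P[[paste0("sh_b_", l)]]
    act <- actFun(pre, cfg$activation)
    mask <- dropMask(length(act), cfg$dropout, stochastic)
    caches[[l]] <- list(input = a, pre = pre, mask = mask)
    a <- act * mask
  }
  lf <- nH + 1L
  z <- as.numeric(P[[paste0("sh_W_", lf)]] %*% a) + P[[paste0("sh_b_", lf)]]
  list(z = z, lastInput = a, caches = caches)
}

sharedBackward <- function(dz, fw, P, cfg, g) {
  nH <- length(fw$caches)
  lf <- nH + 1L
  addGrad(g, paste0("sh_W_", lf), dz %o% fw$lastInput)
  addGrad(g, paste0("sh_b_", lf), dz)
  da <- as.numeric(t(P[[paste0("sh_W_", lf)]]) %*% dz)
  for (l in rev(seq_len(nH))) {
    cc <- fw$caches[[l]]
    dpre <- da * cc$mask * actGrad(cc$pre, cfg$activation)
    addGrad(g, paste0("sh_W_", l), dpre %o% cc$input)
    addGrad(g, paste0("sh_b_", l), dpre)
    da <- as.numeric(t(P[[paste0("sh_W_", l)]]) %*% dpre)
  }
  invisible(NULL)
}

## ---- exported single-modality encoders ---------------------------------

#' Encode one modality of a patient into the shared latent space
#'
#' These run the corresponding encoder of an \linkS4class{OncoModel} in
#' deterministic (dropout-off) mode and return a
#' \linkS4class{ModalityEmbedding}.
#'
#' @param x the modality content: an (H, W, C) array for
#'   \code{encodeImage}, a 0-based integer token vector for
#'   \code{encodeGenomic}, a numeric feature vector for
#'   \code{encodeClinical}.
#' @param model an \linkS4class{OncoModel} with \code{style = "tailored"}.
#' @param patientId identifier carried on the embedding.
#' @return a \linkS4class{ModalityEmbedding} of length \code{d}.
#' @name encodeModality
NULL

#' @rdname encodeModality
#' @export
encodeImage <- function(x, model, patientId = "") {
  stopifnot(is(model, "OncoModel"))
  fw <- imgForward(x, model@params, model@encoderConfig, model@inputSpec)
  new("ModalityEmbedding", vector = fw$z, modality = "image",
      patientId = patientId, present = TRUE)
}

#' @rdname encodeModality
#' @export
encodeGenomic <- function(x, model, patientId = "") {
  stopifnot(is(model, "OncoModel"))
  fw <- genForward(as.integer(x), model@params, model@encoderConfig,
                   model@inputSpec)
  new("ModalityEmbedding", vector = fw$z, modality = "genomic",
      patientId = patientId, present = TRUE)
}

#' @rdname encodeModality
#' @export
encodeClinical <- function(x, model, patientId = "") {
  stopifnot(is(model, "OncoModel"))
  fw <- clinForward(as.numeric(x), model@params, model@encoderConfig,
                    model@inputSpec, stochastic = FALSE)
  new("ModalityEmbedding", vector = fw$z, modality = "clinical",
      patientId = patientId, present = TRUE)
}

## ---- contrastive alignment ---------------------------------------------

#' Contrastive (triplet margin) cross-modal alignment loss
#'
#' Default semantics follow the standard triplet ordering
#' \deqn{\max(0,\ \tau + \|Z_a - Z^+\|^2 - \|Z_a - Z^-\|^2),}
#' which pulls the anchor towards its matched (same-patient, other-modality)
#' positive and pushes it away from the mismatched negative.  The
#' \code{literal = TRUE} flag swaps the two squared distances, reproducing a
#' sign convention that rewards anchor-positive distance; it exists only so
#' the alternative form can be inspected, and is not used in training.
#'
#' @param anchor,positive,negative equal-length numeric embeddings.
#' @param margin nonnegative margin \eqn{\tau}.
#' @param literal use the swapped sign convention?
#' @return a nonnegative scalar.
#' @export
#' @examples
#' contrastiveAlignmentLoss(c(0, 0), c(0.5, 0.5), c(0.4, 0.2), margin = 1)
contrastiveAlignmentLoss <- function(anchor, positive, negative, margin,
                                     literal = FALSE) {
  a <- asEmbeddingVector(anchor)
  p <- asEmbeddingVector(positive)
  n <- asEmbeddingVector(negative)
  if (length(a) != length(p) || length(a) != length(n))
    stop("anchor, positive and negative must have equal length")
  if (margin < 0) stop("'margin' must be >= 0")
  dp <- sum((a - p)^2)
  dn <- sum((a - n)^2)
  if (literal) max(0, margin + dn - dp) else max(0, margin + dp - dn)
}

## Accept either a bare numeric vector or a ModalityEmbedding.
asEmbeddingVector <- function(x) {
  if (is(x, "ModalityEmbedding")) x@vector else as.numeric(x)
}
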
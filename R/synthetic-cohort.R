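#' Construct domain-shift parameters
#'
#' @param targetFraction proportion of patients assigned to the target
#'   domain, in [0, 1].
#' @param meanShift additive offset applied to target-domain image
#'   intensities and clinical features.
#' @param scaleShift multiplicative factor (> 0) applied to the same.
#' @return a \linkS4class{DomainShiftParams}.
#' @export
#' @examples
#' domainShiftParams(targetFraction = 0.25, meanShift = 2)
domainShiftParams <- function(targetFraction = 0.5, meanShift = 0,
                              scaleShift = 1) {
  new("DomainShiftParams", targetFraction = targetFraction,
      meanShift = meanShift, scaleShift = scaleShift)
}

#' Construct a synthetic cohort configuration
#'
#' Defines the study conditions of a synthetic multimodal cohort: three
#' modalities (a small single-channel image, a genomic token sequence, a
#' clinical feature vector), K diagnostic classes, per-modality signal
#' weights, Gaussian noise, an optional source/target covariate shift and
#' random modality missingness.  Identical configurations (including the
#' seed) generate bit-identical cohorts.
#'
#' @param nPatients number of patients (>= 1).
#' @param imageShape integer (height, width, channels).
#' @param genomicLength number of genomic tokens m per patient.
#' @param vocabSize genomic vocabulary size.
#' @param clinicalDim number of clinical features p.
#' @param nClasses number of diagnostic classes K (>= 2).
#' @param informativeness length-3 numeric in [0, 1]: signal weight of the
#'   image, genomic and clinical streams.  0 means the modality is pure
#'   noise; 1 means full class signal.
#' @param noiseSd standard deviation of the additive noise on the image and
#'   clinical modalities.
#' @param shift a \linkS4class{DomainShiftParams}.
#' @param missingRate probability that each modality of each patient is
#'   masked absent (with at least one modality always retained).
#' @param seed integer RNG seed.
#' @return a validated \linkS4class{CohortConfig}.
#' @export
#' @examples
#' cfg <- cohortConfig(nPatients = 50, nClasses = 2, seed = 7)
#' cfg
cohortConfig <- function(nPatients = 200L,
                         imageShape = c(8L, 8L, 1L),
                         genomicLength = 16L,
                         vocabSize = 12L,
                         clinicalDim = 8L,
                         nClasses = 2L,
                         informativeness = c(image = 0.8, genomic = 0.8,
                                             clinical = 0.8),
                         noiseSd = 1,
                         shift = domainShiftParams(),
                         missingRate = 0,
                         seed = 1L) {
  if (!is.numeric(informativeness) || length(informativeness) != 3L)
    stop("'informativeness' must be 3 weights (image, genomic, clinical)")
  inf <- as.numeric(informativeness)
  names(inf) <- MODALITIES
  new("CohortConfig",
      nPatients = checkCount(nPatients, "nPatients"),
      imageShape = as.integer(imageShape),
      genomicLength = checkCount(genomicLength, "genomicLength"),
      vocabSize = checkCount(vocabSize, "vocabSize", min = 2L),
      clinicalDim = checkCount(clinicalDim, "clinicalDim"),
      nClasses = checkCount(nClasses, "nClasses", min = 2L),
      informativeness = inf,
      noiseSd = noiseSd,
      shift = shift,
      missingRate = missingRate,
      seed = as.numeric(seed))
}

#' Construct a patient sample
#'
#' @param patientId character identifier.
#' @param image numeric (H, W, C) array.
#' @param genomic integer token vector (0-based).
#' @param clinical numeric feature vector.
#' @param label 0-based class index.
#' @param domainId "source" or "target".
#' @param modalityMask named logical of length 3.
#' @return a validated \linkS4class{PatientSample}.
#' @export
patientSample <- function(patientId, image, genomic, clinical, label,
                          domainId = "source",
                          modalityMask = c(image = TRUE, genomic = TRUE,
                                           clinical = TRUE)) {
  mask <- as.logical(modalityMask)
  names(mask) <- MODALITIES
  new("PatientSample", patientId = as.character(patientId),
      image = image, genomic = as.integer(genomic),
      clinical = as.numeric(clinical), label = as.integer(label),
      domainId = domainId, modalityMask = mask)
}

## Fixed low-frequency 2-d cosine basis used to render class prototypes as
## spatial image patterns.  Basis l has frequency pair (fh, fw) taken from a
## fixed enumeration, so the rendering is deterministic and config-free.
imageBasis <- function(h, w, nBasis) {
  freqs <- expand.grid(fh = 0:3, fw = 0:3)
  freqs <- freqs[order(freqs$fh + freqs$fw, freqs$fh), , drop = FALSE]
  freqs <- freqs[seq_len(min(nBasis, nrow(freqs))), , drop = FALSE]
  hh <- (seq_len(h) - 0.5) / h
  ww <- (seq_len(w) - 0.5) / w
  vapply(seq_len(nrow(freqs)), function(l) {
    outer(cos(pi * freqs$fh[l] * hh), cos(pi * freqs$fw[l] * ww))
  }, matrix(0, h, w))  # h x w x nBasis
}

## Latent prototype dimension shared by all modality renderings.
PROTO_DIM <- 8L

#' Generate a synthetic multimodal cohort
#'
#' Draws one latent prototype vector per class, then renders each patient's
#' three modalities from their class prototype: the image is the prototype
#' expanded over a fixed low-frequency cosine basis, the genomic sequence is
#' sampled from a class-conditional categorical distribution whose logits
#' are a fixed linear map of the prototype, and the clinical vector is a
#' fixed affine map of the prototype.  Each continuous modality's content is
#' \code{informativeness * rendering + Normal(0, noiseSd)}; for the discrete
#' genomic modality the informativeness weight scales the categorical logits
#' (0 gives uniform tokens).  Class labels are uniform over K.  After a
#' seeded shuffle the first \code{floor(targetFraction * n)} patients are
#' assigned to the target domain and their image and clinical features are
#' shifted by \code{scaleShift * x + meanShift}.  Finally modality
#' missingness is applied at \code{missingRate}.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @return an \linkS4class{OncoCohort}.
#' @export
#' @examples
#' cohort <- generateCohort(cohortConfig(nPatients = 20, seed = 7))
#' cohort
generateCohort <- function(config) {
  if (!is(config, "CohortConfig")) stop("'config' must be a CohortConfig")
  validObject(config)
  h <- config@imageShape[1L]; w <- config@imageShape[2L]
  ch <- config@imageShape[3L]
  n <- config@nPatients; K <- config@nClasses
  inf <- config@informativeness

  set.seed(config@seed)
  ## Class prototypes and fixed rendering maps (drawn once per cohort).
  protos <- matrix(rnorm(K * PROTO_DIM), K, PROTO_DIM)
  basis <- imageBasis(h, w, PROTO_DIM)          # h x w x PROTO_DIM
  genMap <- matrix(rnorm(PROTO_DIM * config@vocabSize), PROTO_DIM,
                   config@vocabSize)
  clinMap <- matrix(rnorm(PROTO_DIM * config@clinicalDim), PROTO_DIM,
                    config@clinicalDim)
  clinOff <- rnorm(config@clinicalDim, sd = 0.5)

  labels <- sample.int(K, n, replace = TRUE) - 1L
  ## Deterministic domain assignment: first floor(fraction * n) patients
  ## after a seeded shuffle become the target domain.
  nTarget <- floor(config@shift@targetFraction * n)
  ord <- sample.int(n)
  domains <- rep("source", n)
  domains[ord[seq_len(nTarget)]] <- "target"

  basisFlat <- matrix(basis, h * w, PROTO_DIM)
  samp <- vector("list", n)
  for (i in seq_len(n)) {
    proto <- protos[labels[i] + 1L, ]
    imgPat <- as.numeric(basisFlat %*% proto) / sqrt(PROTO_DIM)
    img <- inf["image"] * imgPat + rnorm(h * w * ch, sd = config@noiseSd)
    img <- array(rep(img, length.out = h * w * ch), dim = c(h, w, ch))
    tokProb <- softmaxVec(inf["genomic"] * as.numeric(proto %*% genMap))
    gen <- sample.int(config@vocabSize, config@genomicLength,
                      replace = TRUE, prob = tokProb) - 1L
    clin <- inf["clinical"] * (as.numeric(proto %*% clinMap) + clinOff) +
      rnorm(config@clinicalDim, sd = config@noiseSd)
    if (domains[i] == "target") {
      img <- config@shift@scaleShift * img + config@shift@meanShift
      clin <- config@shift@scaleShift * clin + config@shift@meanShift
    }
    samp[[i]] <- patientSample(sprintf("P%04d", i), img, gen, clin,
                               labels[i], domains[i])
  }
  cohort <- new("OncoCohort", samples = samp, config = config)
  if (config@missingRate > 0)
    cohort <- applyMissingness(cohort, config@missingRate,
                               seed = deriveSeed(config@seed, 17L))
  cohort
}

#' Apply random modality missingness
#'
#' Each modality flag of each patient is independently set absent with
#' probability \code{missingRate}.  If all three would be absent, one
#' uniformly chosen modality is restored, so every patient keeps at least
#' one input stream.  Absent modalities have their content replaced by a
#' zero-filled sentinel; downstream code must consult the mask, never the
#' sentinel values.
#'
#' @param cohort an \linkS4class{OncoCohort} (or list of
#'   \linkS4class{PatientSample}).
#' @param missingRate probability in [0, 1].
#' @param seed RNG seed for the missingness draws.
#' @return object of the same type with updated masks and sentinel content.
#' @export
applyMissingness <- function(cohort, missingRate, seed = 1L) {
  checkProb(missingRate, "missingRate")
  asCohort <- is(cohort, "OncoCohort")
  samp <- if (asCohort) cohort@samples else cohort
  set.seed(seed)
  for (i in seq_along(samp)) {
    s <- samp[[i]]
    drop <- runif(3L) < missingRate
    if (all(drop)) drop[sample.int(3L, 1L)] <- FALSE
    mask <- !drop
    names(mask) <- MODALITIES
    if (!mask["image"]) s@image <- array(0, dim = dim(s@image))
    if (!mask["genomic"]) s@genomic <- integer(length(s@genomic))
    if (!mask["clinical"]) s@clinical <- numeric(length(s@clinical))
    s@modalityMask <- mask
    samp[[i]] <- s
  }
  if (asCohort) {
    cohort@samples <- samp
    cohort
  } else samp
}
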
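#' Domain-shift parameters
#'
#' Describes the covariate shift applied to the target-domain half of a
#' synthetic cohort: a fraction of patients is relabelled "target" and their
#' image intensities and clinical features are transformed
#' \eqn{x \mapsto \mathrm{scaleShift}\cdot x + \mathrm{meanShift}}.  Genomic
#' token identities are never shifted; the shift emulates acquisition-level
#' differences (scanners, assay platforms), not biological change.
#'
#' @slot targetFraction proportion of patients assigned to the target domain.
#' @slot meanShift additive offset applied to target-domain features.
#' @slot scaleShift multiplicative factor (> 0) applied to target features.
#' @export
setClass("DomainShiftParams",
  representation(targetFraction = "numeric",
                 meanShift = "numeric",
                 scaleShift = "numeric"),
  prototype(targetFraction = 0.5, meanShift = 0, scaleShift = 1))

setValidity("DomainShiftParams", function(object) {
  msg <- character()
  if (length(object@targetFraction) != 1L || is.na(object@targetFraction) ||
      object@targetFraction < 0 || object@targetFraction > 1)
    msg <- c(msg, "targetFraction must be a single value in [0, 1]")
  if (length(object@scaleShift) != 1L || is.na(object@scaleShift) ||
      object@scaleShift <= 0)
    msg <- c(msg, "scaleShift must be a single value > 0")
  if (length(object@meanShift) != 1L || is.na(object@meanShift))
    msg <- c(msg, "meanShift must be a single finite value")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort configuration
#'
#' Full description of a synthetic multimodal cohort: dimensions of the
#' three modalities, number of diagnostic classes, per-modality signal
#' weights, noise level, domain shift, missingness rate and the seed that
#' makes generation bit-reproducible.
#'
#' @slot nPatients number of patients.
#' @slot imageShape integer (height, width, channels).
#' @slot genomicLength number of genomic tokens per patient.
#' @slot vocabSize genomic token vocabulary size.
#' @slot clinicalDim number of clinical features.
#' @slot nClasses number of diagnostic classes (K >= 2).
#' @slot informativeness named numeric, per-modality signal weight in [0, 1]
#'   for image, genomic and clinical streams.
#' @slot noiseSd standard deviation of additive Gaussian noise on the
#'   continuous modalities.
#' @slot shift a \linkS4class{DomainShiftParams}.
#' @slot missingRate per-modality missingness probability in [0, 1].
#' @slot seed integer RNG seed.
#' @export
setClass("CohortConfig",
  representation(nPatients = "integer",
                 imageShape = "integer",
                 genomicLength = "integer",
                 vocabSize = "integer",
                 clinicalDim = "integer",
                 nClasses = "integer",
                 informativeness = "numeric",
                 noiseSd = "numeric",
                 shift = "DomainShiftParams",
                 missingRate = "numeric",
                 seed = "numeric"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (length(object@nPatients) != 1L || object@nPatients < 1L)
    msg <- c(msg, "nPatients must be >= 1")
  if (length(object@imageShape) != 3L || any(object@imageShape < 1L))
    msg <- c(msg, "imageShape must be 3 positive integers (H, W, C)")
  if (length(object@genomicLength) != 1L || object@genomicLength < 1L)
    msg <- c(msg, "genomicLength must be >= 1")
  if (length(object@vocabSize) != 1L || object@vocabSize < 2L)
    msg <- c(msg, "vocabSize must be >= 2")
  if (length(object@clinicalDim) != 1L || object@clinicalDim < 1L)
    msg <- c(msg, "clinicalDim must be >= 1")
  if (length(object@nClasses) != 1L || object@nClasses < 2L)
    msg <- c(msg, "nClasses must be >= 2")
  if (length(object@informativeness) != 3L ||
      any(object@informativeness < 0 | object@informativeness > 1))
    msg <- c(msg, "informativeness must be 3 weights in [0, 1]")
  if (length(object@noiseSd) != 1L || object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be >= 0")
  if (length(object@missingRate) != 1L || object@missingRate < 0 ||
      object@missingRate > 1)
    msg <- c(msg, "missingRate must be in [0, 1]")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' One patient's multimodal record
#'
#' @slot patientId character identifier.
#' @slot image numeric array of dimension (H, W, C).
#' @slot genomic integer token sequence (0-based tokens).
#' @slot clinical numeric feature vector.
#' @slot label 0-based class index.
#' @slot domainId "source" or "target".
#' @slot modalityMask named logical (image, genomic, clinical); TRUE when
#'   the modality was observed.  Absent modalities carry zero-filled
#'   sentinel content that downstream code must never interpret.
#' @export
setClass("PatientSample",
  representation(patientId = "character",
                 image = "array",
                 genomic = "integer",
                 clinical = "numeric",
                 label = "integer",
                 domainId = "character",
                 modalityMask = "logical"))

setValidity("PatientSample", function(object) {
  msg <- character()
  if (length(object@modalityMask) != 3L ||
      !identical(names(object@modalityMask), MODALITIES))
    msg <- c(msg, "modalityMask must be named (image, genomic, clinical)")
  else if (!any(object@modalityMask))
    msg <- c(msg, "at least one modality must be present")
  if (length(object@label) != 1L || object@label < 0L)
    msg <- c(msg, "label must be a single 0-based class index")
  if (!object@domainId %in% c("source", "target"))
    msg <- c(msg, "domainId must be 'source' or 'target'")
  if (length(dim(object@image)) != 3L)
    msg <- c(msg, "image must be a 3-d array (H, W, C)")
  if (length(msg)) msg else TRUE
})

#' A synthetic multimodal cohort
#'
#' A list of \linkS4class{PatientSample} objects together with the
#' \linkS4class{CohortConfig} that generated (or describes) them.
#'
#' @slot samples list of \linkS4class{PatientSample}.
#' @slot config the generating \linkS4class{CohortConfig}.
#' @export
setClass("OncoCohort",
  representation(samples = "list", config = "CohortConfig"))

setValidity("OncoCohort", function(object) {
  ok <- vapply(object@samples, is, logical(1), "PatientSample")
  if (!all(ok)) return("all samples must be PatientSample objects")
  TRUE
})

#' A modality embedding in the shared latent space
#'
#' @slot vector length-d numeric embedding.
#' @slot modality one of "image", "genomic", "clinical" (or "shared" for the
#'   flattened-input baseline encoder).
#' @slot patientId originating patient.
#' @slot present FALSE when the modality was masked absent (the vector is
#'   then a zero sentinel and must be ignored by fusion).
#' @export
setClass("ModalityEmbedding",
  representation(vector = "numeric",
                 modality = "character",
                 patientId = "character",
                 present = "logical"))

setValidity("ModalityEmbedding", function(object) {
  if (object@present && any(!is.finite(object@vector)))
    return("embedding entries must be finite")
  TRUE
})

#' Attention-fusion output for one patient
#'
#' @slot zFused fused length-d vector.
#' @slot alpha named per-modality attention weights (0 for absent ones);
#'   sums to 1 over present modalities.
#' @slot scores named raw attention scores e_i = w'Z_i (NA for absent).
#' @slot logits length-K classifier scores.
#' @slot probabilities softmax class probabilities.
#' @export
setClass("FusionOutput",
  representation(zFused = "numeric",
                 alpha = "numeric",
                 scores = "numeric",
                 logits = "numeric",
                 probabilities = "numeric"))

setValidity("FusionOutput", function(object) {
  msg <- character()
  if (any(object@alpha < -1e-9) || abs(sum(object@alpha) - 1) > 1e-9)
    msg <- c(msg, "alpha must be nonnegative and sum to 1")
  if (any(object@probabilities < -1e-9) ||
      abs(sum(object@probabilities) - 1) > 1e-9)
    msg <- c(msg, "probabilities must be nonnegative and sum to 1")
  if (length(msg)) msg else TRUE
})

#' Monte-Carlo-dropout predictive estimate
#'
#' @slot mean length-K mean class probabilities over T stochastic passes.
#' @slot variance per-class empirical variance across passes.
#' @slot entropy Shannon entropy (nats) of the mean prediction.
#' @slot passes number of stochastic forward passes T.
#' @slot seed the seed used for the dropout draws.
#' @export
setClass("PredictiveEstimate",
  representation(mean = "numeric",
                 variance = "numeric",
                 entropy = "numeric",
                 passes = "integer",
                 seed = "numeric"))

setValidity("PredictiveEstimate", function(object) {
  msg <- character()
  if (abs(sum(object@mean) - 1) > 1e-9)
    msg <- c(msg, "mean prediction must sum to 1")
  if (any(object@variance < -1e-12))
    msg <- c(msg, "variances must be nonnegative")
  if (object@entropy < -1e-12 || object@entropy > log(length(object@mean)) + 1e-9)
    msg <- c(msg, "entropy must lie in [0, log K]")
  if (length(msg)) msg else TRUE
})

#' Trained multimodal fusion model
#'
#' Holds all trainable parameters (encoders, attention vector, classifier
#' head, optional domain discriminator), the architecture and training
#' configuration, the input dimensions, and the per-epoch training log.
#'
#' @slot params named list of numeric arrays (all trainable parameters).
#' @slot encoderConfig architecture description (see \code{encoderConfig}).
#' @slot trainConfig training hyperparameters (see \code{trainConfig}).
#' @slot inputSpec list: imageShape, genomicLength, vocabSize, clinicalDim,
#'   nClasses.
#' @slot log data.frame with one row per training epoch.
#' @slot trained logical; some reporting functions require a trained model.
#' @export
setClass("OncoModel",
  representation(params = "list",
                 encoderConfig = "list",
                 trainConfig = "list",
                 inputSpec = "list",
                 log = "data.frame",
                 trained = "logical"))

#' Tabular Markov decision process
#'
#' @slot states character state labels.
#' @slot actions character action labels.
#' @slot trans transition array P[s, a, s'] with stochastic rows.
#' @slot reward reward array r(s, a, s') of the same dimension.
#' @slot gamma discount factor in (0, 1].
#' @slot terminal character subset of states.
#' @slot initDist initial state distribution.
#' @export
setClass("MDPSpec",
  representation(states = "character",
                 actions = "character",
                 trans = "array",
                 reward = "array",
                 gamma = "numeric",
                 terminal = "character",
                 initDist = "numeric"))

setValidity("MDPSpec", function(object) {
  msg <- character()
  nS <- length(object@states); nA <- length(object@actions)
  if (!identical(dim(object@trans), c(nS, nA, nS)))
    msg <- c(msg, "trans must have dimension (|S|, |A|, |S|)")
  else {
    sums <- apply(object@trans, c(1, 2), sum)
    if (any(abs(sums - 1) > 1e-9))
      msg <- c(msg, "each P(.|s,a) must sum to 1")
    if (any(object@trans < 0))
      msg <- c(msg, "transition probabilities must be nonnegative")
  }
  if (!identical(dim(object@reward), c(nS, nA, nS)))
    msg <- c(msg, "reward must have dimension (|S|, |A|, |S|)")
  if (length(object@gamma) != 1L || object@gamma <= 0 || object@gamma > 1)
    msg <- c(msg, "gamma must be in (0, 1]")
  if (!all(object@terminal %in% object@states))
    msg <- c(msg, "terminal states must be states")
  if (length(object@initDist) != nS || abs(sum(object@initDist) - 1) > 1e-9 ||
      any(object@initDist < 0))
    msg <- c(msg, "initDist must be a probability vector over states")
  if (length(msg)) msg else TRUE
})

#' Classification metrics report
#'
#' @slot accuracy overall accuracy in [0, 1].
#' @slot macroRecall unweighted mean of per-class recalls.
#' @slot macroF1 unweighted mean of per-class F1 scores.
#' @slot macroAUC unweighted mean of one-vs-rest AUCs.
#' @slot perClass data.frame with class, support, recall, precision, f1, auc.
#' @slot nSamples number of evaluated samples.
#' @export
setClass("MetricsReport",
  representation(accuracy = "numeric",
                 macroRecall = "numeric",
                 macroF1 = "numeric",
                 macroAUC = "numeric",
                 perClass = "data.frame",
                 nSamples = "integer"))

## ---- show methods -------------------------------------------------------

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nPatients, "patients,",
      object@nClasses, "classes\n")
  cat("  image ", paste(object@imageShape, collapse = "x"),
      ", genomic m=", object@genomicLength, " (vocab ", object@vocabSize,
      "), clinical p=", object@clinicalDim, "\n", sep = "")
  cat("  informativeness:",
      paste(sprintf("%s=%.2f", MODALITIES, object@informativeness),
            collapse = ", "), "\n")
  cat("  noiseSd=", object@noiseSd, ", missingRate=", object@missingRate,
      ", seed=", object@seed, "\n", sep = "")
  cat("  shift: targetFraction=", object@shift@targetFraction,
      ", meanShift=", object@shift@meanShift,
      ", scaleShift=", object@shift@scaleShift, "\n", sep = "")
})

setMethod("show", "OncoCohort", function(object) {
  n <- length(object@samples)
  cat("OncoCohort with", n, "patients\n")
  if (n > 0) {
    dom <- table(vapply(object@samples, function(s) s@domainId, character(1)))
    cat("  domains:", paste(names(dom), dom, sep = "=", collapse = ", "), "\n")
    lab <- table(vapply(object@samples, function(s) s@label, integer(1)))
    cat("  labels: ", paste(names(lab), lab, sep = ":", collapse = ", "), "\n")
  }
})

setMethod("show", "PatientSample", function(object) {
  cat("PatientSample", object@patientId,
      sprintf("(label %d, %s)", object@label, object@domainId), "\n")
  cat("  present:",
      paste(MODALITIES[object@modalityMask], collapse = ", "), "\n")
})

setMethod("show", "FusionOutput", function(object) {
  cat("FusionOutput\n  alpha:",
      paste(sprintf("%s=%.3f", names(object@alpha), object@alpha),
            collapse = ", "), "\n")
  cat("  predicted class:", which.max(object@probabilities) - 1L,
      sprintf("(p=%.3f)", max(object@probabilities)), "\n")
})

setMethod("show", "PredictiveEstimate", function(object) {
  cat("PredictiveEstimate over", object@passes, "MC passes\n")
  cat("  mean:", paste(sprintf("%.3f", object@mean), collapse = " "), "\n")
  cat("  entropy:", sprintf("%.4f nats", object@entropy), "\n")
})

setMethod("show", "OncoModel", function(object) {
  np <- sum(vapply(object@params, length, integer(1)))
  cat("OncoModel (", if (object@trained) "trained" else "untrained", ", ",
      np, " parameters)\n", sep = "")
  cat("  d =", object@encoderConfig$d,
      ", K =", object@inputSpec$nClasses, "\n")
  if (nrow(object@log) > 0)
    cat("  epochs trained:", nrow(object@log),
        sprintf(", final loss %.4f", utils::tail(object@log$loss, 1)), "\n")
})

setMethod("show", "MDPSpec", function(object) {
  cat("MDPSpec:", length(object@states), "states,",
      length(object@actions), "actions, gamma =", object@gamma, "\n")
  cat("  terminal:", paste(object@terminal, collapse = ", "), "\n")
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(
    "MetricsReport (n=%d): accuracy %.4f, macro recall %.4f, macro F1 %.4f, macro AUC %.4f\n",
    object@nSamples, object@accuracy, object@macroRecall, object@macroF1,
    object@macroAUC))
})

## ---- accessors ----------------------------------------------------------

#' Accessors for OncoFusion S4 objects
#'
#' @param x an object.
#' @return \code{samples} returns the list of \linkS4class{PatientSample};
#'   \code{cohortConfigOf} the \linkS4class{CohortConfig};
#'   \code{modelParams} the parameter list; \code{trainingLog} the per-epoch
#'   log; \code{alphaWeights} the attention weights of a
#'   \linkS4class{FusionOutput}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setMethod("samples", "OncoCohort", function(x) x@samples)

#' @rdname accessors
#' @export
setGeneric("cohortConfigOf", function(x) standardGeneric("cohortConfigOf"))
#' @rdname accessors
#' @export
setMethod("cohortConfigOf", "OncoCohort", function(x) x@config)

#' @rdname accessors
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))
#' @rdname accessors
#' @export
setMethod("modelParams", "OncoModel", function(x) x@params)

#' @rdname accessors
#' @export
setGeneric("trainingLog", function(x) standardGeneric("trainingLog"))
#' @rdname accessors
#' @export
setMethod("trainingLog", "OncoModel", function(x) x@log)

#' @rdname accessors
#' @export
setGeneric("alphaWeights", function(x) standardGeneric("alphaWeights"))
#' @rdname accessors
#' @export
setMethod("alphaWeights", "FusionOutput", function(x) x@alpha)

#' Number of patients in a cohort
#' @param x an \linkS4class{OncoCohort}.
#' @export
setMethod("length", "OncoCohort", function(x) length(x@samples))

#' Extract one patient from a cohort
#' @param x an \linkS4class{OncoCohort}.
#' @param i index.
#' @export
setMethod("[[", "OncoCohort", function(x, i) x@samples[[i]])
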
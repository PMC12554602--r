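#' Evaluate a model on a cohort
#'
#' Computes accuracy, macro (unweighted) recall, macro F1 and macro
#' one-vs-rest AUC.  In "deterministic" mode dropout is off; in "mc" mode
#' each patient's prediction is the seeded MC-dropout mean.  Argmax ties
#' are broken towards the lowest class index.  Per-class AUC uses the
#' rank-based (Mann-Whitney) estimator, which equals trapezoidal
#' integration of the one-vs-rest ROC curve over unique thresholds.
#' Classes absent from the cohort are excluded from the macro averages
#' with a warning.
#'
#' @param model a trained \linkS4class{OncoModel}.
#' @param cohort nonempty \linkS4class{OncoCohort}.
#' @param mode "deterministic" or "mc".
#' @param T MC passes for "mc" mode.
#' @param seed seed for "mc" mode.
#' @return a \linkS4class{MetricsReport}.
#' @export
evaluateModel <- function(model, cohort,
                          mode = c("deterministic", "mc"), T = 20L,
                          seed = 1L) {
  mode <- match.arg(mode)
  samp <- cohort@samples
  if (!length(samp)) stop("cannot evaluate on an empty cohort")
  K <- model@inputSpec$nClasses
  probs <- matrix(0, length(samp), K)
  for (i in seq_along(samp)) {
    probs[i, ] <- if (mode == "deterministic")
      sampleForward(model@params, model@encoderConfig, model@inputSpec,
                    samp[[i]], stochastic = FALSE)$probs
    else mcDropoutPredict(model, samp[[i]], T = T,
                          seed = deriveSeed(seed, i))@mean
  }
  labels <- vapply(samp, function(s) s@label, integer(1))
  metricsFromProbs(probs, labels, K)
}

## Core metric computation shared by evaluateModel and the ablation runner.
metricsFromProbs <- function(probs, labels, K) {
  pred <- max.col(probs, ties.method = "first") - 1L
  n <- length(labels)
  acc <- mean(pred == labels)
  presentClasses <- sort(unique(labels))
  if (length(presentClasses) < K)
    warning("classes absent from the cohort are excluded from macro ",
            "averages: ",
            paste(setdiff(0:(K - 1L), presentClasses), collapse = ", "))
  rows <- lapply(presentClasses, function(k) {
    tp <- sum(pred == k & labels == k)
    fn <- sum(pred != k & labels == k)
    fp <- sum(pred == k & labels != k)
    recall <- tp / (tp + fn)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    auc <- ovrAUC(probs[, k + 1L], labels == k)
    data.frame(class = k, support = tp + fn, recall = recall,
               precision = precision, f1 = f1, auc = auc)
  })
  perClass <- do.call(rbind, rows)
  new("MetricsReport",
      accuracy = acc,
      macroRecall = mean(perClass$recall),
      macroF1 = mean(perClass$f1),
      macroAUC = mean(perClass$auc, na.rm = TRUE),
      perClass = perClass,
      nSamples = as.integer(n))
}

## Rank-based one-vs-rest AUC (equivalent to the trapezoidal ROC area).
ovrAUC <- function(score, isPos) {
  n1 <- sum(isPos); n0 <- sum(!isPos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[isPos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Exponential moving average of model weights
#'
#' \eqn{\mathrm{ema} \leftarrow \mathrm{decay}\cdot\mathrm{ema} +
#' (1-\mathrm{decay})\cdot\mathrm{current}}, elementwise, recursing through
#' parameter lists.  decay = 0 copies the current weights; decay = 1 leaves
#' the EMA unchanged.
#'
#' @param ema current EMA (numeric array or named list thereof).
#' @param current current weights of identical shape.
#' @param decay in [0, 1].
#' @return updated EMA of the same shape.
#' @export
emaUpdate <- function(ema, current, decay = 0.99) {
  checkProb(decay, "decay")
  if (is.list(ema)) {
    if (!is.list(current) || length(ema) != length(current))
      stop("EMA and current parameter lists have different shapes")
    return(mapply(emaUpdate, ema, current,
                  MoreArgs = list(decay = decay), SIMPLIFY = FALSE))
  }
  if (length(ema) != length(current))
    stop("EMA and current weights have different lengths")
  decay * ema + (1 - decay) * current
}

## ---- cohort splitting ---------------------------------------------------

#' Split a cohort into train / validation / test
#'
#' Seeded patient-level shuffle followed by a 70/15/15 (by default)
#' partition.
#'
#' @param cohort an \linkS4class{OncoCohort}.
#' @param props length-3 positive proportions (normalized to sum 1).
#' @param seed shuffle seed.
#' @return list of three \linkS4class{OncoCohort}s: train, validation,
#'   test.
#' @export
splitCohort <- function(cohort, props = c(0.70, 0.15, 0.15), seed = 1L) {
  if (length(props) != 3L || any(props < 0) || sum(props) <= 0)
    stop("'props' must be 3 nonnegative proportions")
  props <- props / sum(props)
  n <- length(cohort@samples)
  set.seed(seed)
  ord <- sample.int(n)
  nTrain <- floor(props[1L] * n)
  nVal <- floor(props[2L] * n)
  mk <- function(idx) new("OncoCohort", samples = cohort@samples[idx],
                          config = cohort@config)
  list(train = mk(ord[seq_len(nTrain)]),
       validation = mk(ord[nTrain + seq_len(nVal)]),
       test = mk(ord[(nTrain + nVal + 1L):n]))
}

## ---- ablation runner ----------------------------------------------------

ABLATION_VARIANTS <- c("full", "no_fusion_attention", "no_tailored_encoders",
                       "no_policy", "no_domain_adaptation",
                       "cnn_mlp_baseline")

## Apply a named variant's component toggles to (encoder, train, policy).
applyVariant <- function(variant, encoder, train, policyEnabled) {
  switch(variant,
    full = {},
    no_fusion_attention = { encoder$fusion <- "uniform" },
    no_tailored_encoders = { encoder$style <- "shared" },
    no_policy = { policyEnabled <- FALSE },
    no_domain_adaptation = {
      train$daWeight <- 0; train$consistencyWeight <- 0
    },
    cnn_mlp_baseline = {
      encoder$style <- "shared"; encoder$fusion <- "uniform"
      train$daWeight <- 0; train$consistencyWeight <- 0
      train$contrastiveWeight <- 0; train$calibrationWeight <- 0
      policyEnabled <- FALSE
    },
    stop("unknown ablation variant '", variant, "'"))
  list(encoder = encoder, train = train, policyEnabled = policyEnabled)
}

#' Run an ablation comparison
#'
#' Trains and evaluates every (variant, seed) pair on the same synthetic
#' cohort and the same train/test split, then tabulates mean and standard
#' deviation of the test metrics per variant.  Variant semantics:
#' \code{no_fusion_attention} replaces softmax attention by a uniform mean
#' over present modalities; \code{no_tailored_encoders} replaces the three
#' modality encoders by one shared MLP on the flattened concatenated
#' inputs; \code{no_policy} skips the treatment-policy stage;
#' \code{no_domain_adaptation} disables the adversarial and consistency
#' terms; \code{cnn_mlp_baseline} combines the shared MLP, uniform fusion
#' and no auxiliary losses.  A failing variant run is recorded in the table
#' rather than aborting the sweep.
#'
#' @param cohortCfg a \linkS4class{CohortConfig} for the shared cohort.
#' @param encoder base \code{\link{encoderConfig}}.
#' @param train base \code{\link{trainConfig}}.
#' @param variants character subset of the known variants.
#' @param seeds integer training seeds (>= 1 of them).
#' @return data.frame with one row per variant: mean and sd of accuracy,
#'   macro F1 and macro AUC over seeds, plus an \code{errors} count.
#' @export
runAblation <- function(cohortCfg, encoder = encoderConfig(),
                        train = trainConfig(), variants = "full",
                        seeds = c(1L, 2L, 3L)) {
  stopifnot(length(variants) >= 1L, length(seeds) >= 1L)
  bad <- setdiff(variants, ABLATION_VARIANTS)
  if (length(bad)) stop("unknown variants: ", paste(bad, collapse = ", "))
  cohort <- generateCohort(cohortCfg)
  split <- splitCohort(cohort, seed = deriveSeed(cohortCfg@seed, 101L))
  rows <- lapply(variants, function(v) {
    cfgs <- applyVariant(v, encoder, train, TRUE)
    acc <- f1 <- auc <- rep(NA_real_, length(seeds))
    errors <- 0L
    for (j in seq_along(seeds)) {
      res <- tryCatch({
        m <- trainFusionModel(split$train, cfgs$encoder, cfgs$train,
                              seed = seeds[j])
        evaluateModel(m, split$test)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors <- errors + 1L
        warning("variant '", v, "' seed ", seeds[j], " failed: ",
                conditionMessage(res))
      } else {
        acc[j] <- res@accuracy; f1[j] <- res@macroF1; auc[j] <- res@macroAUC
      }
    }
    data.frame(variant = v,
               meanAccuracy = mean(acc, na.rm = TRUE),
               sdAccuracy = stats::sd(acc[!is.na(acc)]),
               meanMacroF1 = mean(f1, na.rm = TRUE),
               sdMacroF1 = stats::sd(f1[!is.na(f1)]),
               meanMacroAUC = mean(auc, na.rm = TRUE),
               sdMacroAUC = stats::sd(auc[!is.na(auc)]),
               nSeeds = length(seeds), errors = errors)
  })
  do.call(rbind, rows)
}

## ---- case-level attention report ---------------------------------------

#' Case-level attention and uncertainty report
#'
#' Machine-readable per-patient report: modality attention weights,
#' per-modality MC-dropout variances and inverse-variance weights, class
#' probabilities, normalized predictive entropy and a gradient-x-input
#' saliency vector per present modality (absent modalities report weight 0
#' and null saliency).  Saliency holds the attention weights fixed and
#' propagates the predicted-class logit gradient to each raw input.
#'
#' @param model a trained \linkS4class{OncoModel} (tailored encoders).
#' @param sample a \linkS4class{PatientSample}.
#' @param T MC-dropout passes for the variance estimates.
#' @param seed RNG seed.
#' @return a nested list, serializable with \code{jsonlite::toJSON}.
#' @export
attentionReport <- function(model, sample, T = 20L, seed = 1L) {
  if (!isTRUE(model@trained))
    stop("attentionReport requires a trained model")
  if (model@encoderConfig$style != "tailored")
    stop("attentionReport requires the tailored encoders")
  P <- model@params; cfg <- model@encoderConfig; spec <- model@inputSpec
  fwd <- sampleForward(P, cfg, spec, sample, stochastic = FALSE)
  predClass <- which.max(fwd$probs) - 1L
  sigma2 <- modalityVariance(model, sample, T = T, seed = seed)
  ivw <- inverseVarianceWeights(sigma2)

  ## gradient-x-input saliency per present modality, attention held fixed
  dzf <- as.numeric(P$out_W[predClass + 1L, ])
  saliency <- stats::setNames(vector("list", 3L), MODALITIES)
  for (m in MODALITIES) {
    if (!fwd$present[[m]]) next
    dz <- fwd$alpha[[m]] * dzf * fwd$embMasks[[m]]
    g <- newGradEnv(P)
    sal <- switch(m,
      image = {
        dx <- imgBackward(dz, fwd$enc$image, P, cfg, g, inputGrad = TRUE)
        as.numeric(dx) * as.numeric(sample@image)
      },
      genomic = {
        dX0 <- genBackward(dz, fwd$enc$genomic, P, cfg, g,
                           inputGrad = TRUE)
        rowSums(dX0 * fwd$enc$genomic$X0)  # per-token saliency
      },
      clinical = {
        dc <- clinBackward(dz, fwd$enc$clinical, P, cfg, g,
                           inputGrad = TRUE)
        dc * sample@clinical
      })
    saliency[[m]] <- sal
  }
  list(patient_id = sample@patientId,
       predicted_class = predClass,
       probabilities = as.numeric(fwd$probs),
       attention = as.list(fwd$alpha),
       sigma2 = as.list(sigma2),
       inverse_variance_weights = as.list(ivw),
       normalized_entropy = shannonEntropy(fwd$probs, normalized = TRUE),
       saliency = saliency,
       mc_passes = T, seed = seed)
}

## ---- checkpoint I/O -----------------------------------------------------

CHECKPOINT_VERSION <- 1L

#' Save / load a model checkpoint
#'
#' Checkpoints are versioned JSON files holding every parameter array (with
#' dimensions), the architecture and training configuration, the input
#' dimensions and the training log; numbers are written at full precision
#' so a round trip reproduces the model exactly.
#'
#' @param model an \linkS4class{OncoModel}.
#' @param path JSON file path.
#' @return \code{saveCheckpoint} the path invisibly; \code{loadCheckpoint}
#'   an \linkS4class{OncoModel}.
#' @name checkpointIO
NULL

#' @rdname checkpointIO
#' @export
saveCheckpoint <- function(model, path) {
  params <- lapply(model@params, function(p)
    list(dim = if (is.matrix(p)) dim(p) else length(p),
         data = as.numeric(p)))
  obj <- list(version = CHECKPOINT_VERSION,
              encoderConfig = model@encoderConfig,
              trainConfig = model@trainConfig,
              inputSpec = model@inputSpec,
              trained = model@trained,
              log = model@log,
              params = params)
  ## I(17) = 17 significant digits, enough for a bit-exact double round trip
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname checkpointIO
#' @param path JSON file path.
#' @export
loadCheckpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$version) || obj$version > CHECKPOINT_VERSION)
    stop("unsupported checkpoint version: ", obj$version)
  params <- lapply(obj$params, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[1L], p$dim[2L])
    else as.numeric(p$data)
  })
  enc <- obj$encoderConfig
  for (f in c("d")) enc[[f]] <- as.integer(enc[[f]])
  enc$image <- lapply(enc$image, as.integer)
  enc$genomic$embDim <- as.integer(enc$genomic$embDim)
  enc$genomic$nHeads <- as.integer(enc$genomic$nHeads)
  enc$genomic$nLayers <- as.integer(enc$genomic$nLayers)
  enc$genomic$dK <- as.integer(enc$genomic$dK)
  enc$clinical$hidden <- as.integer(enc$clinical$hidden)
  enc$shared$hidden <- as.integer(enc$shared$hidden)
  spec <- obj$inputSpec
  spec$imageShape <- as.integer(spec$imageShape)
  spec$genomicLength <- as.integer(spec$genomicLength)
  spec$vocabSize <- as.integer(spec$vocabSize)
  spec$clinicalDim <- as.integer(spec$clinicalDim)
  spec$nClasses <- as.integer(spec$nClasses)
  lg <- if (is.data.frame(obj$log)) obj$log else data.frame()
  new("OncoModel", params = params, encoderConfig = enc,
      trainConfig = obj$trainConfig, inputSpec = spec,
      log = lg, trained = isTRUE(obj$trained))
}

## ---- config-driven end-to-end run --------------------------------------

RUN_CONFIG_KEYS <- c("version", "cohort", "encoder", "train", "split",
                     "policy", "ema", "seed", "out")

readRunConfig <- function(configPath) {
  cfg <- if (grepl("\\.ya?ml$", configPath))
    yaml::read_yaml(configPath)
  else jsonlite::read_json(configPath, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg
}

buildFromArgs <- function(fn, args, what) {
  args <- args %||% list()
  unknown <- setdiff(names(args), names(formals(fn)))
  if (length(unknown))
    stop("unknown ", what, " config keys: ",
         paste(unknown, collapse = ", "))
  do.call(fn, args)
}

#' Config-driven end-to-end training run
#'
#' Reads a YAML or JSON run configuration, generates the synthetic cohort,
#' splits it, trains the fusion model (with whatever auxiliary terms the
#' config enables, optionally tracking an exponential moving average of the
#' weights at epoch granularity), optionally trains the treatment policy on
#' the toy oncology MDP, evaluates on the test split, and writes a
#' self-describing artifact directory: \code{checkpoint.json},
#' \code{metrics.json}, \code{trainlog.jsonl}, a config copy and a seed /
#' session record.  Re-running the same config and seed reproduces the
#' metrics exactly.
#'
#' Config keys: \code{cohort}, \code{encoder}, \code{train} (arguments of
#' \code{\link{cohortConfig}}, \code{\link{encoderConfig}},
#' \code{\link{trainConfig}}); \code{split} (proportions); \code{policy}
#' (\code{enabled} plus \code{\link{policyConfig}} arguments); \code{ema}
#' (\code{enabled}, \code{decay}); \code{seed}; \code{out}.  Unknown keys
#' raise a schema error naming them.
#'
#' @param configPath path to a YAML/JSON config file.
#' @param outDir output directory (overrides the config's \code{out}).
#' @param seed seed (overrides the config's \code{seed}).
#' @return the artifact directory path, invisibly; the metrics are also
#'   returned in the \code{"metrics"} attribute.
#' @export
runTraining <- function(configPath, outDir = NULL, seed = NULL) {
  cfg <- readRunConfig(configPath)
  seed <- seed %||% cfg$seed %||% 1L
  outDir <- outDir %||% cfg$out %||% stop("no output directory configured")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  shiftArgs <- cfg$cohort$shift
  cohortArgs <- cfg$cohort
  cohortArgs$shift <- NULL
  cohortCfg <- do.call(cohortConfig,
                       c(cohortArgs,
                         if (!is.null(shiftArgs))
                           list(shift = buildFromArgs(domainShiftParams,
                                                      shiftArgs, "shift"))))
  encoder <- buildFromArgs(encoderConfig, cfg$encoder, "encoder")
  train <- buildFromArgs(trainConfig, cfg$train, "train")

  cohort <- generateCohort(cohortCfg)
  props <- cfg$split %||% c(0.70, 0.15, 0.15)
  split <- splitCohort(cohort, props = as.numeric(unlist(props)),
                       seed = deriveSeed(seed, 101L))

  emaCfg <- cfg$ema %||% list(enabled = FALSE)
  if (isTRUE(emaCfg$enabled)) {
    decay <- emaCfg$decay %||% 0.99
    epochs <- train$epochs
    perEpoch <- train; perEpoch$epochs <- 1L
    model <- NULL; ema <- NULL; logs <- list()
    for (ep in seq_len(epochs)) {
      model <- if (is.null(model))
        trainFusionModel(split$train, encoder, perEpoch, seed = seed)
      else trainFusionModel(split$train, seed = deriveSeed(seed, ep),
                            model = model)
      ema <- if (is.null(ema)) model@params
             else emaUpdate(ema, model@params, decay)
      logs[[ep]] <- model@log
    }
    model@log <- do.call(rbind, logs)
    model@log$epoch <- seq_len(nrow(model@log))
    model@params <- ema
  } else {
    model <- trainFusionModel(split$train, encoder, train, seed = seed)
  }

  metrics <- list(
    validation = metricsAsList(evaluateModel(model, split$validation)),
    test = metricsAsList(evaluateModel(model, split$test)))

  policyCfgIn <- cfg$policy %||% list(enabled = FALSE)
  if (isTRUE(policyCfgIn$enabled)) {
    pcArgs <- policyCfgIn; pcArgs$enabled <- NULL
    pc <- buildFromArgs(policyConfig, pcArgs, "policy")
    pc$seed <- deriveSeed(seed, 999L)
    pol <- trainQLearning(toyOncologyMdp(), pc)
    metrics$policy <- list(
      meanReturnLast100 = mean(utils::tail(pol$log$return_, 100L)),
      supNormVsValueIteration =
        max(abs(pol$Q - valueIteration(toyOncologyMdp()))))
  }

  saveCheckpoint(model, file.path(outDir, "checkpoint.json"))
  jsonlite::write_json(metrics, file.path(outDir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(
    vapply(seq_len(nrow(model@log)), function(i)
      jsonlite::toJSON(as.list(model@log[i, ]), auto_unbox = TRUE,
                       digits = NA),
      character(1)),
    file.path(outDir, "trainlog.jsonl"))
  file.copy(configPath, file.path(outDir, basename(configPath)),
            overwrite = TRUE)
  jsonlite::write_json(
    list(seed = seed,
         package_version = as.character(utils::packageVersion("OncoFusion")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), tz = "UTC")),
    file.path(outDir, "runinfo.json"), auto_unbox = TRUE)
  out <- outDir
  attr(out, "metrics") <- metrics
  invisible(out)
}

metricsAsList <- function(m) {
  list(accuracy = m@accuracy, macroRecall = m@macroRecall,
       macroF1 = m@macroF1, macroAUC = m@macroAUC,
       nSamples = m@nSamples)
}
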
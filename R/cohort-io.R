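## Cohort serialization: plain UTF-8 tab-delimited text plus a JSON config.
##
## Layout of a cohort directory:
##   manifest.tsv  patient_id, label, domain_id, mask_image, mask_genomic,
##                 mask_clinical (one row per patient; authoritative order)
##   clinical.tsv  patient_id + p named feature columns
##   genomic.tsv   patient_id + space-separated 0-based integer tokens
##   images.tsv    patient_id + H*W*C pixel columns in R array (column-major)
##                 order; this is the multi-array container keyed by patient
##   config.json   the generating CohortConfig
##
## Numeric fields are written with 17 significant digits so that
## readCohort(writeCohort(x)) reproduces x exactly.

fmtNum <- function(x) sprintf("%.17g", x)

#' Write a cohort to a directory of text files
#'
#' @param cohort an \linkS4class{OncoCohort}.
#' @param path directory to create/populate.
#' @return the path, invisibly.
#' @seealso \code{\link{readCohort}}
#' @export
writeCohort <- function(cohort, path) {
  if (!is(cohort, "OncoCohort")) stop("'cohort' must be an OncoCohort")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cfg <- cohort@config
  samp <- cohort@samples

  manifest <- data.frame(
    patient_id = vapply(samp, function(s) s@patientId, character(1)),
    label = vapply(samp, function(s) s@label, integer(1)),
    domain_id = vapply(samp, function(s) s@domainId, character(1)),
    mask_image = vapply(samp, function(s) s@modalityMask[["image"]], logical(1)),
    mask_genomic = vapply(samp, function(s) s@modalityMask[["genomic"]], logical(1)),
    mask_clinical = vapply(samp, function(s) s@modalityMask[["clinical"]], logical(1)),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(path, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  p <- cfg@clinicalDim
  clin <- do.call(rbind, c(lapply(samp, function(s) fmtNum(s@clinical)),
                           list(matrix(character(), 0L, p))))
  clinDf <- data.frame(patient_id = manifest$patient_id, clin,
                       stringsAsFactors = FALSE)
  names(clinDf) <- c("patient_id", paste0("c", seq_len(p)))
  utils::write.table(clinDf, file.path(path, "clinical.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  genDf <- data.frame(
    patient_id = manifest$patient_id,
    tokens = vapply(samp, function(s) paste(s@genomic, collapse = " "),
                    character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(genDf, file.path(path, "genomic.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  npix <- prod(cfg@imageShape)
  img <- do.call(rbind, c(lapply(samp, function(s) fmtNum(as.numeric(s@image))),
                          list(matrix(character(), 0L, npix))))
  imgDf <- data.frame(patient_id = manifest$patient_id, img,
                      stringsAsFactors = FALSE)
  names(imgDf) <- c("patient_id", paste0("px", seq_len(npix)))
  utils::write.table(imgDf, file.path(path, "images.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  cfgList <- list(nPatients = cfg@nPatients,
                  imageShape = cfg@imageShape,
                  genomicLength = cfg@genomicLength,
                  vocabSize = cfg@vocabSize,
                  clinicalDim = cfg@clinicalDim,
                  nClasses = cfg@nClasses,
                  informativeness = as.list(cfg@informativeness),
                  noiseSd = cfg@noiseSd,
                  shift = list(targetFraction = cfg@shift@targetFraction,
                               meanShift = cfg@shift@meanShift,
                               scaleShift = cfg@shift@scaleShift),
                  missingRate = cfg@missingRate,
                  seed = cfg@seed)
  jsonlite::write_json(cfgList, file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort written by \code{writeCohort}
#'
#' Validates that every patient listed in the manifest has matching records
#' in the clinical, genomic and image tables and that array shapes agree
#' with the stored configuration; mismatches raise a parse error naming the
#' offending patient.
#'
#' @param path cohort directory.
#' @return an \linkS4class{OncoCohort}.
#' @export
readCohort <- function(path) {
  need <- c("manifest.tsv", "clinical.tsv", "genomic.tsv", "images.tsv",
            "config.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop("cohort directory is missing: ", paste(missing, collapse = ", "))

  cj <- jsonlite::read_json(file.path(path, "config.json"),
                            simplifyVector = TRUE)
  config <- cohortConfig(
    nPatients = max(1L, cj$nPatients), imageShape = cj$imageShape,
    genomicLength = cj$genomicLength, vocabSize = cj$vocabSize,
    clinicalDim = cj$clinicalDim, nClasses = cj$nClasses,
    informativeness = unlist(cj$informativeness),
    noiseSd = cj$noiseSd,
    shift = domainShiftParams(cj$shift$targetFraction, cj$shift$meanShift,
                              cj$shift$scaleShift),
    missingRate = cj$missingRate, seed = cj$seed)

  manifest <- utils::read.table(file.path(path, "manifest.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE,
                                colClasses = c("character", "integer",
                                               "character", "logical",
                                               "logical", "logical"))
  readTab <- function(f) {
    d <- utils::read.table(file.path(path, f), sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
    rownames(d) <- d$patient_id
    d
  }
  clin <- readTab("clinical.tsv")
  gen <- readTab("genomic.tsv")
  img <- readTab("images.tsv")

  npix <- prod(config@imageShape)
  if (nrow(manifest) > 0 && ncol(img) - 1L != npix)
    stop("image table has ", ncol(img) - 1L,
         " pixel columns but config implies ", npix)
  if (nrow(manifest) > 0 && ncol(clin) - 1L != config@clinicalDim)
    stop("clinical table has ", ncol(clin) - 1L,
         " feature columns but config implies ", config@clinicalDim)

  samp <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    pid <- manifest$patient_id[i]
    for (tab in list(clinical = clin, genomic = gen, images = img)) {
      if (!pid %in% rownames(tab))
        stop("manifest references patient '", pid,
             "' absent from a modality table")
    }
    gtok <- as.integer(strsplit(gen[pid, "tokens"], " ", fixed = TRUE)[[1]])
    if (length(gtok) != config@genomicLength)
      stop("patient '", pid, "': token sequence length ", length(gtok),
           " does not match config (", config@genomicLength, ")")
    samp[[i]] <- patientSample(
      patientId = pid,
      image = array(as.numeric(img[pid, -1L]), dim = config@imageShape),
      genomic = gtok,
      clinical = as.numeric(clin[pid, -1L]),
      label = manifest$label[i],
      domainId = manifest$domain_id[i],
      modalityMask = c(image = manifest$mask_image[i],
                       genomic = manifest$mask_genomic[i],
                       clinical = manifest$mask_clinical[i]))
  }
  new("OncoCohort", samples = samp, config = config)
}
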
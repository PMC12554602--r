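test_that("identical configurations generate bit-identical cohorts", {
  cfg <- tinyCohortConfig(nPatients = 15L, seed = 7L, missingRate = 0.2)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(length(a), length(b))
  for (i in seq_len(length(a))) {
    expect_identical(a[[i]]@image, b[[i]]@image)
    expect_identical(a[[i]]@genomic, b[[i]]@genomic)
    expect_identical(a[[i]]@clinical, b[[i]]@clinical)
    expect_identical(a[[i]]@label, b[[i]]@label)
    expect_identical(a[[i]]@domainId, b[[i]]@domainId)
    expect_identical(a[[i]]@modalityMask, b[[i]]@modalityMask)
  }
})

test_that("invalid configurations raise errors naming the field", {
  expect_error(cohortConfig(nPatients = 0), "nPatients")
  expect_error(cohortConfig(nClasses = 1), "nClasses")
  expect_error(cohortConfig(informativeness = c(2, 0, 0)),
               "informativeness")
  expect_error(cohortConfig(missingRate = 1.5), "missingRate")
  expect_error(domainShiftParams(scaleShift = 0), "scaleShift")
  expect_error(domainShiftParams(targetFraction = -0.1), "targetFraction")
})

test_that("domain assignment gives exactly floor(fraction * n) targets", {
  cfg <- tinyCohortConfig(
    nPatients = 200L, seed = 3L,
    shift = domainShiftParams(targetFraction = 0.25))
  co <- generateCohort(cfg)
  dom <- vapply(samples(co), function(s) s@domainId, character(1))
  expect_identical(sum(dom == "target"), 50L)
})

test_that("labels are uniform over classes (3 standard errors)", {
  K <- 4L
  n <- 10000L
  cfg <- cohortConfig(nPatients = n, imageShape = c(2L, 2L, 1L),
                      genomicLength = 2L, vocabSize = 3L, clinicalDim = 2L,
                      nClasses = K, seed = 13L)
  co <- generateCohort(cfg)
  lab <- vapply(samples(co), function(s) s@label, integer(1))
  se <- sqrt((1 / K) * (1 - 1 / K) / n)
  for (k in 0:(K - 1L))
    expect_lt(abs(mean(lab == k) - 1 / K), 3 * se)
})

test_that("with an identity shift, source and target distributions agree", {
  cfg <- cohortConfig(nPatients = 2000L, imageShape = c(2L, 2L, 1L),
                      genomicLength = 2L, vocabSize = 3L, clinicalDim = 3L,
                      nClasses = 2L, seed = 5L,
                      shift = domainShiftParams(targetFraction = 0.5,
                                                meanShift = 0,
                                                scaleShift = 1))
  co <- generateCohort(cfg)
  dom <- vapply(samples(co), function(s) s@domainId, character(1))
  clin <- t(vapply(samples(co), function(s) s@clinical, numeric(3)))
  for (j in 1:3) {
    ms <- mean(clin[dom == "source", j]); mt <- mean(clin[dom == "target", j])
    se <- sqrt(stats::var(clin[, j]) * (1 / sum(dom == "source") +
                                          1 / sum(dom == "target")))
    expect_lt(abs(ms - mt), 3 * se)
  }
})

test_that("missingness honors the rate and the at-least-one rule", {
  co <- generateCohort(tinyCohortConfig(nPatients = 10L, seed = 2L))
  ## rate 0: identity
  same <- applyMissingness(co, 0, seed = 1L)
  expect_identical(
    lapply(samples(same), function(s) s@modalityMask),
    lapply(samples(co), function(s) s@modalityMask))
  ## rate 1: exactly one modality survives per patient
  one <- applyMissingness(co, 1, seed = 1L)
  for (s in samples(one)) expect_identical(sum(s@modalityMask), 1L)
  ## absent modalities carry a zero sentinel
  s1 <- samples(one)[[1]]
  for (m in c("image", "genomic", "clinical")) {
    if (!s1@modalityMask[[m]]) {
      content <- slot(s1, m)
      expect_true(all(content == 0))
    }
  }
  ## empirical rate: post-restoration absence probability is
  ## rate - rate^3 / 3 (one of three restored when all three drop)
  n <- 1000L
  big <- generateCohort(tinyCohortConfig(nPatients = n, seed = 11L))
  rate <- 0.3
  out <- applyMissingness(big, rate, seed = 21L)
  absent <- vapply(samples(out), function(s) sum(!s@modalityMask),
                   numeric(1))
  pAbs <- rate - rate^3 / 3
  se <- sqrt(pAbs * (1 - pAbs) / (3 * n))
  expect_lt(abs(mean(absent) / 3 - pAbs), 3 * se)
  expect_error(applyMissingness(co, 1.2), "missingRate")
})

test_that("cohort write/read round-trips every field", {
  cfg <- tinyCohortConfig(nPatients = 10L, seed = 9L, missingRate = 0.3)
  co <- generateCohort(cfg)
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  back <- readCohort(dir)
  expect_identical(length(back), length(co))
  for (i in seq_len(length(co))) {
    expect_identical(back[[i]]@patientId, co[[i]]@patientId)
    expect_identical(back[[i]]@image, co[[i]]@image)
    expect_identical(back[[i]]@genomic, co[[i]]@genomic)
    expect_identical(back[[i]]@clinical, co[[i]]@clinical)
    expect_identical(back[[i]]@label, co[[i]]@label)
    expect_identical(back[[i]]@domainId, co[[i]]@domainId)
    expect_identical(back[[i]]@modalityMask, co[[i]]@modalityMask)
  }
})

test_that("a manifest referencing a missing patient names it", {
  co <- generateCohort(tinyCohortConfig(nPatients = 3L, seed = 1L))
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  img <- readLines(file.path(dir, "images.tsv"))
  writeLines(img[-2L], file.path(dir, "images.tsv"))  # drop patient P0001
  expect_error(readCohort(dir), "P0001")
})

test_that("an empty cohort writes a valid manifest and reads back empty", {
  cfg <- tinyCohortConfig(nPatients = 5L)
  empty <- new("OncoCohort", samples = list(), config = cfg)
  dir <- withr::local_tempdir()
  writeCohort(empty, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_identical(length(readCohort(dir)), 0L)
})

test_that("zero informativeness yields label-independent modalities", {
  ## with no signal, a Bayes-optimal single-modality classifier is at
  ## chance; check that class-conditional clinical means are indistinct
  cfg <- cohortConfig(nPatients = 1500L, imageShape = c(2L, 2L, 1L),
                      genomicLength = 4L, vocabSize = 4L, clinicalDim = 3L,
                      nClasses = 2L, informativeness = c(0, 0, 0),
                      noiseSd = 1, seed = 17L)
  co <- generateCohort(cfg)
  lab <- vapply(samples(co), function(s) s@label, integer(1))
  clin <- t(vapply(samples(co), function(s) s@clinical, numeric(3)))
  for (j in 1:3) {
    d <- mean(clin[lab == 0L, j]) - mean(clin[lab == 1L, j])
    se <- sqrt(stats::var(clin[, j]) * (1 / sum(lab == 0L) +
                                          1 / sum(lab == 1L)))
    expect_lt(abs(d), 3 * se)
  }
})
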
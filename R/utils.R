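#' @keywords internal
#' @import methods
"_PACKAGE"

## Canonical modality order used throughout the package.
MODALITIES <- c("image", "genomic", "clinical")

#' Numerically stable softmax
#'
#' @param x numeric vector of scores.
#' @return probability vector summing to 1.
#' @keywords internal
softmaxVec <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1L)
  if (any(!is.finite(x))) stop("softmax input contains non-finite values")
  z <- exp(x - max(x))
  z / sum(z)
}

## Row-wise softmax of a matrix.
softmaxRows <- function(m) {
  mx <- apply(m, 1L, max)
  z <- exp(m - mx)
  z / rowSums(z)
}

#' Shannon entropy of a probability vector
#'
#' Computes \eqn{-\sum_k p_k \log p_k} in nats with the convention
#' \eqn{0 \log 0 = 0}.  With \code{normalized = TRUE} the value is divided
#' by \eqn{\log(\mathrm{length}(p))} so that the uniform distribution maps
#' to 1 regardless of length (length-1 vectors have entropy 0 by
#' convention).
#'
#' @param p probability vector (nonnegative, sums to 1 up to tolerance).
#' @param normalized divide by the maximum attainable entropy?
#' @return nonnegative scalar.
#' @export
shannonEntropy <- function(p, normalized = FALSE) {
  if (any(p < 0)) stop("entropy requires nonnegative entries")
  s <- sum(p)
  if (abs(s - 1) > 1e-6) stop("entropy input must sum to 1 (got ", format(s), ")")
  nz <- p > 0
  h <- -sum(p[nz] * log(p[nz]))
  if (normalized) {
    if (length(p) > 1L) h <- h / log(length(p)) else h <- 0
  }
  h
}

## Derive a child seed from a base seed; kept below 2^31.
deriveSeed <- function(seed, salt) {
  (as.numeric(seed) * 7919 + as.numeric(salt) * 104729) %% 2147483647
}

## Validate a scalar probability-like argument.
checkProb <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("'", name, "' must be a single number in [0, 1]", call. = FALSE)
  invisible(x)
}

checkCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop("'", name, "' must be an integer >= ", min, call. = FALSE)
  invisible(as.integer(x))
}

## Mean of a numeric vector that errors on empties (guards against silent NaN).
meanStrict <- function(x) {
  if (length(x) == 0L) stop("mean over an empty set")
  mean(x)
}
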
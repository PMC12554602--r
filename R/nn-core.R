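## Minimal neural-network primitives with hand-derived backpropagation.
## All parameters live in a flat named list of numeric matrices/vectors;
## gradients are accumulated into an environment holding the same names.

actFun <- function(x, name) {
  switch(name,
    relu = pmax(x, 0),
    gelu = x * stats::pnorm(x),
    identity = x,
    stop("unknown activation '", name, "'"))
}

## derivative of the activation evaluated at pre-activation x
actGrad <- function(x, name) {
  switch(name,
    relu = as.numeric(x > 0),
    gelu = stats::pnorm(x) + x * stats::dnorm(x),
    identity = rep(1, length(x)),
    stop("unknown activation '", name, "'"))
}

glorot <- function(nout, nin) {
  matrix(stats::rnorm(nout * nin, sd = sqrt(2 / (nin + nout))), nout, nin)
}

## ---- convolution plumbing ----------------------------------------------

## Patch-extraction index table for a (h, w, ch) array with square kernel k
## and stride s (valid padding).  Row j of $idx holds the linear indices of
## patch j in the flattened input; cached per geometry.
.im2colCache <- new.env(parent = emptyenv())

im2colIndex <- function(h, w, ch, k, stride) {
  key <- paste(h, w, ch, k, stride, sep = "_")
  hit <- .im2colCache[[key]]
  if (!is.null(hit)) return(hit)
  outH <- floor((h - k) / stride) + 1L
  outW <- floor((w - k) / stride) + 1L
  if (outH < 1L || outW < 1L)
    stop("kernel ", k, " with stride ", stride,
         " does not fit input ", h, "x", w)
  np <- outH * outW
  idx <- matrix(0L, np, k * k * ch)
  j <- 0L
  for (ow in seq_len(outW)) for (oh in seq_len(outH)) {
    j <- j + 1L
    rows <- (oh - 1L) * stride + seq_len(k)
    cols <- (ow - 1L) * stride + seq_len(k)
    cell <- 0L
    for (cc in seq_len(ch)) for (jc in cols) for (ir in rows) {
      cell <- cell + 1L
      idx[j, cell] <- ir + (jc - 1L) * h + (cc - 1L) * h * w
    }
  }
  res <- list(idx = idx, outH = outH, outW = outW)
  .im2colCache[[key]] <- res
  res
}

## ---- sinusoidal positional encoding ------------------------------------

posEncoding <- function(m, e) {
  pos <- seq_len(m) - 1L
  pe <- matrix(0, m, e)
  for (j in seq_len(e)) {
    i <- (j - 1L) %/% 2L
    angle <- pos / (10000 ^ (2 * i / e))
    pe[, j] <- if (j %% 2L == 1L) sin(angle) else cos(angle)
  }
  pe
}

## ---- gradient accumulation ---------------------------------------------

newGradEnv <- function(params) {
  g <- new.env(parent = emptyenv())
  for (nm in names(params)) g[[nm]] <- params[[nm]] * 0
  g
}

addGrad <- function(gradEnv, name, value) {
  gradEnv[[name]] <- gradEnv[[name]] + value
  invisible(NULL)
}

gradAsList <- function(gradEnv, params, scale = 1) {
  out <- vector("list", length(params))
  names(out) <- names(params)
  for (nm in names(params)) out[[nm]] <- gradEnv[[nm]] * scale
  out
}

## ---- Adam optimizer -----------------------------------------------------

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1 ^ t)
    vhat <- state$v[[nm]] / (1 - beta2 ^ t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## Inverted dropout mask: scales kept units by 1/(1-rate) so the expected
## activation is unchanged; identity when rate == 0 or not stochastic.
dropMask <- function(n, rate, stochastic) {
  if (!stochastic || rate <= 0) return(rep(1, n))
  (stats::runif(n) >= rate) / (1 - rate)
}
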
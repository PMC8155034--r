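#' @importFrom stats rnorm runif setNames quantile median sd wilcox.test
#' @importFrom utils read.delim write.table head tail packageVersion
NULL

## Small numerical helpers shared across the network code. Kept internal.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## Row-wise softmax for an n x k matrix, numerically stabilised.
softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

clipProb <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

## Glorot/Xavier uniform initialisation for a fan_in x fan_out matrix.
glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

l2norm <- function(v) sqrt(sum(v^2))

unitVec <- function(v) {
  n <- l2norm(v)
  if (n < 1e-12) c(1, 0, 0) else v / n
}

#' Derive a stage seed from a root seed
#'
#' All randomness in the package flows from a single root seed; per-stage
#' seeds are derived deterministically so that stages can be re-run in
#' isolation. The result always fits in a 32-bit integer.
#'
#' @param seed Integer root seed.
#' @param stage Character stage label.
#' @return An integer seed.
#' @export
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435.0 + h * 97.0) %% 2147480000)
}

## ---- parameter-list algebra (used by both optimisers and the finite
## ---- difference gradient checks) ------------------------------------

paramsToVector <- function(params) {
  unlist(lapply(params, as.numeric), use.names = FALSE)
}

vectorToParams <- function(vec, template) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    piece <- vec[(pos + 1L):(pos + n)]
    if (is.matrix(template[[nm]])) {
      out[[nm]] <- matrix(piece, nrow(template[[nm]]), ncol(template[[nm]]))
    } else {
      out[[nm]] <- piece
    }
    pos <- pos + n
  }
  stopifnot(pos == length(vec))
  out
}

zeroLike <- function(params) {
  lapply(params, function(p) {
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  })
}

addGrads <- function(acc, g) {
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  acc
}

scaleGrads <- function(g, s) lapply(g, function(x) x * s)

## ---- ADAM -----------------------------------------------------------

adamInit <- function(params) {
  list(m = zeroLike(params), v = zeroLike(params), t = 0L)
}

## One ADAM update over a named list of parameter arrays.
adamStep <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / c1
    vhat <- state$v[[nm]] / c2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## ---- early stopping --------------------------------------------------

#' Early-stopping bookkeeping over a validation-loss sequence
#'
#' Given the validation losses observed after each epoch, returns the epoch
#' after which training stops (the first epoch at which the loss has failed
#' to improve for `patience` consecutive epochs, or the last epoch), and the
#' epoch with the best (lowest) validation loss, whose checkpoint is the one
#' a trainer should return.
#'
#' @param losses Numeric vector of per-epoch validation losses.
#' @param patience Number of consecutive non-improving epochs tolerated.
#' @return List with `stop_epoch` and `best_epoch`.
#' @export
earlyStopSchedule <- function(losses, patience = 5L) {
  stopifnot(length(losses) >= 1L, patience >= 1L)
  best <- losses[1L]
  bestEpoch <- 1L
  bad <- 0L
  for (e in seq_along(losses)) {
    if (e == 1L) next
    if (losses[e] < best) {
      best <- losses[e]
      bestEpoch <- e
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) {
        return(list(stop_epoch = e, best_epoch = bestEpoch))
      }
    }
  }
  list(stop_epoch = length(losses), best_epoch = bestEpoch)
}
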
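#' @include AllClasses.R utils.R features.R ontology.R
NULL

#' CNN baseline configuration
#'
#' DeepGO-style sequence-only baseline: parallel one-dimensional
#' convolutions of several filter lengths over the one-hot sequence, ReLU,
#' channel concatenation, global max pooling, and a dense sigmoid head.
#' Desk defaults use 4 filter widths (8, 16, 24, 32) with 64 filters each;
#' the full-scale architecture (16 widths x 512 filters) is reachable
#' through the same knobs.
#'
#' @param filter_widths Integer vector of filter lengths.
#' @param n_filters Filters per width.
#' @return Configuration list.
#' @export
cnnConfig <- function(filter_widths = c(8L, 16L, 24L, 32L),
                      n_filters = 64L) {
  stopifnot(all(filter_widths >= 1L), n_filters >= 1L)
  list(filter_widths = as.integer(filter_widths),
       n_filters = as.integer(n_filters))
}

#' Initialise CNN baseline parameters
#'
#' @param config From [cnnConfig()].
#' @param n_terms Number of output terms.
#' @param seed Integer seed.
#' @param vocab One-hot channel count.
#' @return Named list of parameter arrays.
#' @export
initCNNParams <- function(config, n_terms, seed = 1L, vocab = 26L) {
  withr::with_seed(as.integer(seed), {
    p <- list()
    for (k in seq_along(config$filter_widths)) {
      f <- config$filter_widths[k]
      p[[paste0("Wc", k)]] <- glorot(f * vocab, config$n_filters)
      p[[paste0("bc", k)]] <- numeric(config$n_filters)
    }
    tot <- length(config$filter_widths) * config$n_filters
    p$W_d <- glorot(tot, n_terms)
    p$b_d <- numeric(n_terms)
    p
  })
}

## Build the sliding-window design matrix for a 'same'-padded 1-d
## convolution of width f over the L x vocab one-hot matrix.
im2col <- function(X, f) {
  L <- nrow(X); v <- ncol(X)
  padL <- (f - 1L) %/% 2L
  padR <- f - 1L - padL
  Xp <- rbind(matrix(0, padL, v), X, matrix(0, padR, v))
  M <- matrix(0, L, f * v)
  for (o in seq_len(f))
    M[, ((o - 1L) * v + 1L):(o * v)] <- Xp[o:(o + L - 1L), , drop = FALSE]
  M
}

## Forward pass with cache for the backward pass.
cnnForwardFull <- function(X, params, config) {
  fmax <- max(config$filter_widths)
  if (nrow(X) < fmax) {
    warning(sprintf("sequence of length %d shorter than the largest filter (%d); zero-padded",
                    nrow(X), fmax))
    X <- rbind(X, matrix(0, fmax - nrow(X), ncol(X)))
  }
  pooled <- numeric(0)
  cache <- list(X = X, widths = list())
  for (k in seq_along(config$filter_widths)) {
    f <- config$filter_widths[k]
    M <- im2col(X, f)
    Z <- sweep(M %*% params[[paste0("Wc", k)]], 2L,
               params[[paste0("bc", k)]], "+")
    H <- relu(Z)
    amax <- max.col(t(H), ties.method = "first")   # row index of max per filter
    pmaxv <- H[cbind(amax, seq_len(ncol(H)))]
    pooled <- c(pooled, pmaxv)
    cache$widths[[k]] <- list(M = M, Z = Z, amax = amax)
  }
  logits <- drop(pooled %*% params$W_d) + params$b_d
  p <- sigmoid(logits)
  cache$pooled <- pooled; cache$p <- p
  cache
}

#' Sequence-only CNN baseline forward pass
#'
#' Parallel 1-d convolutions over the sequence axis, ReLU, global max
#' pooling per filter, and a dense sigmoid head giving one probability per
#' term. Sequences shorter than the largest filter are zero-padded with a
#' warning.
#'
#' @param X L x 26 one-hot matrix from [oneHotEncode()].
#' @param params From [initCNNParams()] or a trained [CNNModel-class].
#' @param config From [cnnConfig()].
#' @return Numeric vector of per-term probabilities in (0, 1).
#' @export
cnnBaselineForward <- function(X, params, config) {
  cnnForwardFull(X, params, config)$p
}

## Weighted BCE loss and gradient for one protein (sigmoid head):
## contribution w_j * (y log p + (1-y) log(1-p)).
cnnProteinGrad <- function(X, y, weights, params, config) {
  fw <- cnnForwardFull(X, params, config)
  p <- clipProb(fw$p)
  loss <- -sum(weights * (y * log(p) + (1 - y) * log(1 - p)))
  dlog <- weights * (fw$p - y)
  g <- list()
  g$W_d <- outer(fw$pooled, dlog)
  g$b_d <- dlog
  dpool <- drop(params$W_d %*% dlog)
  nf <- config$n_filters
  for (k in seq_along(config$filter_widths)) {
    wk <- fw$widths[[k]]
    seg <- dpool[((k - 1L) * nf + 1L):(k * nf)]
    dZ <- matrix(0, nrow(wk$Z), ncol(wk$Z))
    sel <- cbind(wk$amax, seq_len(nf))
    dZ[sel] <- seg * (wk$Z[sel] > 0)
    g[[paste0("Wc", k)]] <- crossprod(wk$M, dZ)
    g[[paste0("bc", k)]] <- colSums(dZ)
  }
  list(loss = loss, grads = g[names(params)])
}

cnnBatchLoss <- function(Xs, y, weights, params, config) {
  tot <- 0
  for (i in seq_along(Xs)) {
    p <- clipProb(cnnForwardFull(Xs[[i]], params, config)$p)
    yi <- y[i, ]
    tot <- tot - sum(weights * (yi * log(p) + (1 - yi) * log(1 - p)))
  }
  tot / length(Xs)
}

#' Train the CNN sequence baseline
#'
#' Same optimisation protocol as the GCN: class-weighted cross-entropy,
#' ADAM (learning rate 1e-4, beta1 = beta2 = 0.95, batch size 64), ~10%
#' validation split, early stopping with patience 5, best-validation
#' checkpoint returned. Deterministic given `seed`.
#'
#' @param records List of [ProteinRecord-class] objects with labels.
#' @param labelSpace A [LabelSpace-class].
#' @param config From [cnnConfig()].
#' @param seed Integer seed.
#' @param lr,beta1,beta2,batch_size,max_epochs,patience,validation_fraction
#'   Optimisation settings.
#' @param verbose Print per-epoch losses.
#' @return A [CNNModel-class].
#' @export
trainCNN <- function(records, labelSpace, config = cnnConfig(), seed = 1L,
                     lr = 1e-4, beta1 = 0.95, beta2 = 0.95,
                     batch_size = 64L, max_epochs = 200L, patience = 5L,
                     validation_fraction = 0.1, verbose = FALSE) {
  Xs <- lapply(records, function(r) oneHotEncode(r@sequence))
  yArr <- encodeLabels(records, labelSpace)
  y <- yArr[, , 1, drop = FALSE]
  dim(y) <- dim(yArr)[1:2]
  w <- labelSpace@weights
  n <- length(records)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  result <- withr::with_seed(as.integer(seed), {
    nVal <- max(1L, round(validation_fraction * n))
    valIdx <- sort(sample.int(n, nVal))
    trIdx <- setdiff(seq_len(n), valIdx)
    params <- initCNNParams(config, length(labelSpace@termIds),
                            seed = sample.int(.Machine$integer.max, 1))
    opt <- adamInit(params)
    best <- list(params = params, loss = Inf)
    bad <- 0L
    for (epoch in seq_len(max_epochs)) {
      ord <- sample(trIdx)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      for (b in batches) {
        acc <- zeroLike(params)
        for (i in b)
          acc <- addGrads(acc, cnnProteinGrad(Xs[[i]], y[i, ], w,
                                              params, config)$grads)
        g <- scaleGrads(acc, 1 / length(b))
        upd <- adamStep(params, g, opt, lr, beta1, beta2)
        params <- upd$params; opt <- upd$state
      }
      trLoss <- cnnBatchLoss(Xs[trIdx], y[trIdx, , drop = FALSE], w,
                             params, config)
      valLoss <- cnnBatchLoss(Xs[valIdx], y[valIdx, , drop = FALSE], w,
                              params, config)
      if (!is.finite(trLoss) || !is.finite(valLoss))
        stop(sprintf("training diverged at epoch %d (non-finite loss)", epoch))
      log[nrow(log) + 1L, ] <- list(epoch, trLoss, valLoss)
      if (verbose)
        message(sprintf("CNN epoch %3d  train %.4f  val %.4f", epoch,
                        trLoss, valLoss))
      if (valLoss < best$loss) {
        best <- list(params = params, loss = valLoss)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= patience) break
      }
    }
    best
  })
  new("CNNModel", params = result$params, config = config,
      labelSpace = labelSpace, trainingLog = log)
}
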
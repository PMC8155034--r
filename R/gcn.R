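#' @include AllClasses.R utils.R features.R
NULL

#' Symmetrically normalized adjacency with self-connections
#'
#' Computes `Ahat = D^{-1/2} (A + I) D^{-1/2}` where `D` is the diagonal
#' degree matrix of `A + I`. Self-connections ensure each residue's own
#' features enter its neighbourhood sum; the symmetric normalization bounds
#' the spectrum of `Ahat` by 1.
#'
#' @param A Symmetric binary adjacency with zero diagonal (a bare matrix or
#'   a [ContactMap-class]).
#' @return L x L symmetric non-negative matrix.
#' @export
#' @examples
#' normalizeAdjacency(matrix(c(0, 1, 1, 0), 2))  # all entries 0.5
normalizeAdjacency <- function(A) {
  if (is(A, "ContactMap")) A <- A@adjacency
  if (nrow(A) != ncol(A) || !isTRUE(all.equal(A, t(A))))
    stop("adjacency must be a symmetric square matrix")
  At <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(At))
  At * outer(dinv, dinv)
}

#' One Kipf-Welling graph convolution layer
#'
#' `H_next = ReLU(Ahat H W)`: each residue's output is a weighted sum of
#' its own and its structural neighbours' features, linearly mixed and
#' rectified.
#'
#' @param Ahat Normalized adjacency from [normalizeAdjacency()].
#' @param H L x c_l input feature matrix.
#' @param W c_l x c_next weight matrix.
#' @return L x c_next matrix.
#' @export
graphConvLayer <- function(Ahat, H, W) {
  if (nrow(H) != nrow(Ahat))
    stop("feature rows must match adjacency dimension")
  if (ncol(H) != nrow(W))
    stop(sprintf("feature width %d does not match weight rows %d",
                 ncol(H), nrow(W)))
  relu(Ahat %*% H %*% W)
}

#' Concatenate layer outputs and sum-pool over residues
#'
#' Concatenates the per-layer feature matrices column-wise and sums over
#' residues, giving a fixed-length protein representation; rows excluded by
#' the validity mask (padding) contribute nothing.
#'
#' @param Hlist List of L x c_l matrices sharing the row count L.
#' @param mask Optional logical vector of valid rows.
#' @return Numeric vector of length `sum(c_l)`.
#' @export
concatAndPool <- function(Hlist, mask = NULL) {
  L <- unique(vapply(Hlist, nrow, numeric(1)))
  if (length(L) != 1L) stop("layer outputs have inconsistent row counts")
  Hcat <- do.call(cbind, Hlist)
  if (is.null(mask)) mask <- rep(TRUE, L)
  colSums(Hcat[mask, , drop = FALSE])
}

#' Classification head: FC + per-term two-way softmax
#'
#' `hidden = ReLU(h_pool W_fc + b_fc)`; the second dense layer produces two
#' logits per term, passed through a per-term softmax so each term's
#' (positive, negative) probabilities sum to 1.
#'
#' @param hpool Pooled protein representation vector.
#' @param head Named list with `W_fc`, `b_fc`, `W_out`, `b_out`.
#' @return T x 2 matrix of probabilities, columns `pos`, `neg`.
#' @export
classify <- function(hpool, head) {
  a1 <- drop(hpool %*% head$W_fc) + head$b_fc
  h1 <- relu(a1)
  logits <- drop(h1 %*% head$W_out) + head$b_out
  Tn <- length(logits) / 2L
  P <- softmaxRows(matrix(logits, Tn, 2L))
  colnames(P) <- c("pos", "neg")
  P
}

#' Class-weighted binary cross-entropy of Eq-style paired indicators
#'
#' `L = -(1/N) sum_i sum_j sum_k w_j y_ijk log(yhat_ijk)` with natural
#' logarithms and predicted probabilities clipped to `[eps, 1 - eps]`. The
#' class weight `w_j = N / N_j+` multiplies both the positive and negative
#' indicator of term j.
#'
#' @param yhat Predicted probabilities: N x T x 2 array or T x 2 matrix.
#' @param y True indicators, same shape.
#' @param weights Per-term class weights w_j.
#' @param eps Clipping constant.
#' @return Scalar loss.
#' @export
weightedBceLoss <- function(yhat, y, weights, eps = 1e-7) {
  if (is.matrix(yhat)) {
    yhat <- array(yhat, dim = c(1L, dim(yhat)))
    y <- array(y, dim = dim(yhat))
  }
  stopifnot(all(dim(yhat) == dim(y)), dim(yhat)[2] == length(weights))
  N <- dim(yhat)[1]
  warr <- array(rep(rep(weights, each = N), 2L), dim = dim(yhat))
  -sum(warr * y * log(clipProb(yhat, eps))) / N
}

#' GCN architecture configuration
#'
#' @param n_layers Number of graph convolution layers.
#' @param channels Per-layer channel widths (recycled to `n_layers`).
#' @param c0 Input channel width produced by the feature fusion.
#' @param fc_hidden Hidden width of the post-pooling dense layer.
#' @param useLM Whether the language-model feature pathway is enabled.
#' @param lm_dim Hidden width of the language model (when `useLM`).
#' @param max_len Maximum supported protein length at prediction time.
#' @param layer_variant Tag of the graph propagation rule. The Kipf-Welling
#'   rule is implemented with full gradients; alternative propagation rules
#'   can be plugged in through `layer_fun` for forward-only experimentation.
#' @param layer_fun Optional function `(Ahat, H, W) -> H_next` replacing the
#'   built-in layer in forward passes. Training supports only the built-in
#'   rule.
#' @return Configuration list.
#' @export
gcnConfig <- function(n_layers = 3L, channels = 32L, c0 = 32L,
                      fc_hidden = 64L, useLM = TRUE, lm_dim = 64L,
                      max_len = 1000L, layer_variant = "kipf_welling",
                      layer_fun = NULL) {
  stopifnot(n_layers >= 1L, all(channels >= 1L), c0 >= 1L, fc_hidden >= 1L)
  list(n_layers = as.integer(n_layers),
       channels = rep(as.integer(channels), length.out = n_layers),
       c0 = as.integer(c0), fc_hidden = as.integer(fc_hidden),
       useLM = isTRUE(useLM), lm_dim = if (isTRUE(useLM)) lm_dim else 0L,
       max_len = as.integer(max_len), layer_variant = layer_variant,
       layer_fun = layer_fun)
}

#' Initialise all trainable GCN parameters
#'
#' @param config From [gcnConfig()].
#' @param n_terms Number of output terms.
#' @param seed Integer seed.
#' @return Named list of parameter arrays (fusion, per-layer, head).
#' @export
initGCNParams <- function(config, n_terms, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    p <- initFusionParams(config$lm_dim, config$c0)
    cl <- c(config$c0, config$channels)
    for (l in seq_len(config$n_layers))
      p[[paste0("Wg", l)]] <- glorot(cl[l], cl[l + 1])
    sumC <- sum(config$channels)
    p$W_fc <- glorot(sumC, config$fc_hidden)
    p$b_fc <- numeric(config$fc_hidden)
    p$W_out <- glorot(config$fc_hidden, 2L * n_terms)
    p$b_out <- numeric(2L * n_terms)
    p
  })
}

## Full forward pass for one protein. Returns every intermediate needed by
## the backward pass and by grad-CAM. `feat` is a list with Ahat, X, HLM
## (NULL when the LM pathway is off) and optionally mask.
gcnForward <- function(params, feat, config) {
  mask <- feat$mask
  if (is.null(mask)) mask <- rep(TRUE, nrow(feat$X))
  H0 <- fuseFeatures(feat$HLM, feat$X, params)
  Hs <- vector("list", config$n_layers)
  Ps <- vector("list", config$n_layers)
  Hprev <- H0
  for (l in seq_len(config$n_layers)) {
    if (is.null(config$layer_fun)) {
      Ps[[l]] <- feat$Ahat %*% Hprev
      Hs[[l]] <- relu(Ps[[l]] %*% params[[paste0("Wg", l)]])
    } else {
      Hs[[l]] <- config$layer_fun(feat$Ahat, Hprev,
                                  params[[paste0("Wg", l)]])
    }
    Hprev <- Hs[[l]]
  }
  hpool <- concatAndPool(Hs, mask)
  a1 <- drop(hpool %*% params$W_fc) + params$b_fc
  h1 <- relu(a1)
  logits <- drop(h1 %*% params$W_out) + params$b_out
  Tn <- length(logits) / 2L
  P <- softmaxRows(matrix(logits, Tn, 2L))
  list(H0 = H0, Hs = Hs, Ps = Ps, hpool = hpool, a1 = a1, h1 = h1,
       logits = logits, probs = P, mask = mask)
}

## Backward pass for the weighted softmax cross-entropy of one protein.
## `y` is the T x 2 indicator matrix, `weights` the per-term w_j. Returns
## gradients with the same shapes as `params` (not yet divided by batch N).
gcnBackward <- function(params, feat, fw, y, weights, config) {
  Tn <- nrow(fw$probs)
  G <- (fw$probs - y) * weights            # T x 2, recycled by column
  gLogits <- as.numeric(G)
  grads <- list()
  grads$W_out <- outer(fw$h1, gLogits)
  grads$b_out <- gLogits
  dh1 <- drop(params$W_out %*% gLogits)
  da1 <- dh1 * (fw$a1 > 0)
  grads$W_fc <- outer(fw$hpool, da1)
  grads$b_fc <- da1
  dhpool <- drop(params$W_fc %*% da1)
  L <- nrow(fw$H0)
  offsets <- c(0L, cumsum(config$channels))
  dHnext <- NULL                           # gradient flowing from layer l+1
  for (l in rev(seq_len(config$n_layers))) {
    cols <- (offsets[l] + 1L):offsets[l + 1L]
    dHl <- matrix(dhpool[cols], L, length(cols), byrow = TRUE)
    dHl[!fw$mask, ] <- 0
    if (!is.null(dHnext)) dHl <- dHl + dHnext
    dZ <- dHl * (fw$Hs[[l]] > 0)
    grads[[paste0("Wg", l)]] <- crossprod(fw$Ps[[l]], dZ)
    dHnext <- feat$Ahat %*% (dZ %*% t(params[[paste0("Wg", l)]]))
  }
  dZ0 <- dHnext * (fw$H0 > 0)
  if (!is.null(feat$HLM)) grads$W_LM <- crossprod(feat$HLM, dZ0)
  grads$W_X <- crossprod(feat$X, dZ0)
  grads$b <- colSums(dZ0)
  grads[names(params)]
}

## Loss of a set of proteins for a given parameter list; used by training
## and by the finite-difference gradient checks.
gcnBatchLoss <- function(params, feats, y, weights, config) {
  tot <- 0
  for (i in seq_along(feats)) {
    fw <- gcnForward(params, feats[[i]], config)
    tot <- tot + weightedBceLoss(fw$probs, y[i, , , drop = TRUE] |>
                                   matrix(nrow = dim(y)[2]), weights)
  }
  tot / length(feats)
}

## Mean gradient over a batch.
gcnBatchGrad <- function(params, feats, y, weights, config) {
  acc <- zeroLike(params)
  for (i in seq_along(feats)) {
    fw <- gcnForward(params, feats[[i]], config)
    yi <- matrix(y[i, , , drop = TRUE], nrow = dim(y)[2])
    acc <- addGrads(acc, gcnBackward(params, feats[[i]], fw, yi,
                                     weights, config))
  }
  scaleGrads(acc, 1 / length(feats))
}

#' Featurize protein records for the GCN
#'
#' Builds, per record, the normalized adjacency, the one-hot matrix and
#' (optionally) the frozen language-model feature matrix.
#'
#' @param records List of [ProteinRecord-class] objects with contact maps.
#' @param lm Optional [LanguageModel-class]; `NULL` disables the LM pathway.
#' @return List of per-protein feature lists (`Ahat`, `X`, `HLM`).
#' @export
featurizeRecords <- function(records, lm = NULL) {
  lapply(records, function(r) {
    if (is.null(r@cmap)) stop(sprintf("record %s lacks a contact map", r@id))
    list(Ahat = normalizeAdjacency(r@cmap@adjacency),
         X = oneHotEncode(r@sequence),
         HLM = if (is.null(lm)) NULL else extractLMFeatures(lm, r@sequence))
  })
}

#' Train the GCN function predictor
#'
#' Minimises the class-weighted paired-indicator cross-entropy with ADAM
#' (defaults: learning rate 1e-4, beta1 = beta2 = 0.95, batch size 64),
#' holding out a random ~10% validation split, stopping early when the
#' validation loss fails to improve for `patience` consecutive epochs, and
#' returning the best-validation checkpoint. Deterministic given `seed`.
#'
#' @param records List of [ProteinRecord-class] objects with contact maps
#'   and labels over `labelSpace`.
#' @param labelSpace A [LabelSpace-class].
#' @param config From [gcnConfig()].
#' @param seed Integer seed controlling init, split and batch order.
#' @param lm Optional frozen [LanguageModel-class] (required when
#'   `config$useLM`).
#' @param lr,beta1,beta2 ADAM hyper-parameters.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience.
#' @param validation_fraction Fraction of records held out for validation.
#' @param verbose Print per-epoch losses.
#' @return A [GCNModel-class].
#' @export
trainGCN <- function(records, labelSpace, config = gcnConfig(), seed = 1L,
                     lm = NULL, lr = 1e-4, beta1 = 0.95, beta2 = 0.95,
                     batch_size = 64L, max_epochs = 200L, patience = 5L,
                     validation_fraction = 0.1, verbose = FALSE) {
  if (config$useLM && is.null(lm))
    stop("config enables the LM pathway but no language model was given")
  if (!config$useLM) lm <- NULL
  if (config$useLM && lm@hiddenSize != config$lm_dim)
    stop("language model hidden size does not match config$lm_dim")
  if (!is.null(config$layer_fun))
    stop("training is implemented for the built-in Kipf-Welling layer only")
  feats <- featurizeRecords(records, lm)
  y <- encodeLabels(records, labelSpace)
  w <- labelSpace@weights
  n <- length(records)
  if (n < 2L) stop("need at least 2 records to train")
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  result <- withr::with_seed(as.integer(seed), {
    nVal <- max(1L, round(validation_fraction * n))
    valIdx <- sort(sample.int(n, nVal))
    trIdx <- setdiff(seq_len(n), valIdx)
    params <- initGCNParams(config, length(labelSpace@termIds),
                            seed = sample.int(.Machine$integer.max, 1))
    opt <- adamInit(params)
    best <- list(params = params, loss = Inf, epoch = 0L)
    bad <- 0L
    for (epoch in seq_len(max_epochs)) {
      ord <- sample(trIdx)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      trLoss <- 0
      for (b in batches) {
        g <- gcnBatchGrad(params, feats[b], y[b, , , drop = FALSE], w, config)
        upd <- adamStep(params, g, opt, lr, beta1, beta2)
        params <- upd$params; opt <- upd$state
      }
      trLoss <- gcnBatchLoss(params, feats[trIdx],
                             y[trIdx, , , drop = FALSE], w, config)
      valLoss <- gcnBatchLoss(params, feats[valIdx],
                              y[valIdx, , , drop = FALSE], w, config)
      if (!is.finite(trLoss) || !is.finite(valLoss))
        stop(sprintf("training diverged at epoch %d (non-finite loss)", epoch))
      log[nrow(log) + 1L, ] <- list(epoch, trLoss, valLoss)
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                        trLoss, valLoss))
      if (valLoss < best$loss) {
        best <- list(params = params, loss = valLoss, epoch = epoch)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= patience) break
      }
    }
    best
  })
  new("GCNModel", params = result$params, config = config,
      labelSpace = labelSpace, lm = lm, trainingLog = log)
}

#' Predict term scores and binary calls for one protein
#'
#' The score of a term is its positive-class softmax probability; the
#' binary call requires the score to exceed 0.5 strictly (a score of
#' exactly 0.5 is a negative call).
#'
#' @param model A [GCNModel-class].
#' @param protein A [ProteinRecord-class] with a contact map, or a
#'   prebuilt feature list (`Ahat`, `X`, `HLM`) as produced by
#'   [featurizeRecords()].
#' @return Data frame with `term_id`, `term_name`, `score`, `call`.
#' @export
predictFunctions <- function(model, protein) {
  feat <- if (is(protein, "ProteinRecord")) {
    if (nchar(protein@sequence) > model@config$max_len)
      stop(sprintf("protein length %d exceeds the configured maximum %d",
                   nchar(protein@sequence), model@config$max_len))
    featurizeRecords(list(protein), model@lm)[[1]]
  } else protein
  fw <- gcnForward(model@params, feat, model@config)
  score <- fw$probs[, 1]
  data.frame(term_id = model@labelSpace@termIds,
             term_name = model@labelSpace@termNames,
             score = score, call = score > 0.5,
             stringsAsFactors = FALSE)
}

#' Score a set of proteins
#'
#' @param model A [GCNModel-class] or [CNNModel-class].
#' @param records List of [ProteinRecord-class] objects (or prebuilt
#'   feature lists for a GCN).
#' @return N x T matrix of positive-class scores.
#' @export
scoreProteins <- function(model, records) {
  if (is(model, "CNNModel")) {
    scores <- do.call(rbind, lapply(records, function(r)
      cnnBaselineForward(oneHotEncode(if (is(r, "ProteinRecord"))
        r@sequence else r), model@params, model@config)))
  } else {
    scores <- do.call(rbind, lapply(records, function(r) {
      feat <- if (is(r, "ProteinRecord"))
        featurizeRecords(list(r), model@lm)[[1]] else r
      gcnForward(model@params, feat, model@config)$probs[, 1]
    }))
  }
  colnames(scores) <- model@labelSpace@termIds
  rownames(scores) <- vapply(records, function(r)
    if (is(r, "ProteinRecord")) r@id else NA_character_, character(1))
  scores
}

#' Write predictions as a TSV report
#'
#' One row per (protein, term) with score at or above `floor`; scores above
#' 0.5 are flagged significant.
#'
#' @param scores N x T score matrix from [scoreProteins()].
#' @param labelSpace The matching [LabelSpace-class].
#' @param path Output path.
#' @param floor Reporting floor (default 0.1).
#' @export
writePredictionTable <- function(scores, labelSpace, path, floor = 0.1) {
  idx <- which(scores >= floor, arr.ind = TRUE)
  df <- data.frame(
    protein_id = rownames(scores)[idx[, 1]],
    term_id = labelSpace@termIds[idx[, 2]],
    term_name = labelSpace@termNames[idx[, 2]],
    score = scores[idx],
    significant = scores[idx] > 0.5)
  df <- df[order(df$protein_id, -df$score), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
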
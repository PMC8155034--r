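#' @include AllClasses.R utils.R features.R
NULL

## Two stacked forward LSTM layers over the 26-symbol residue vocabulary,
## trained as a next-residue predictor. Gate layout inside the fused weight
## matrices W1/W2 ((in + h) x 4h): input, forget, cell-candidate, output.

lstmInitParams <- function(hidden, vocab = 26L) {
  list(W1 = glorot(vocab + hidden, 4L * hidden) * 0.5,
       b1 = numeric(4L * hidden),
       W2 = glorot(hidden + hidden, 4L * hidden) * 0.5,
       b2 = numeric(4L * hidden),
       W_o = matrix(0, hidden, vocab),
       b_o = numeric(vocab))
}

## One LSTM cell step for a batch. `x` is B x in, states are B x h.
lstmCell <- function(x, hprev, cprev, W, b, h) {
  z <- sweep(cbind(x, hprev) %*% W, 2L, b, "+")
  i <- sigmoid(z[, 1:h, drop = FALSE])
  f <- sigmoid(z[, (h + 1):(2 * h), drop = FALSE])
  g <- tanh(z[, (2 * h + 1):(3 * h), drop = FALSE])
  o <- sigmoid(z[, (3 * h + 1):(4 * h), drop = FALSE])
  cc <- f * cprev + i * g
  tc <- tanh(cc)
  list(i = i, f = f, g = g, o = o, c = cc, tc = tc, h = o * tc,
       cprev = cprev, hprev = hprev, x = x)
}

tokenize <- function(sequence) {
  vocab <- residueVocabulary()
  idx <- match(strsplit(toupper(sequence), "")[[1]], vocab)
  idx[is.na(idx)] <- length(vocab)
  idx
}

oneHotRows <- function(idx, vocab = 26L) {
  X <- matrix(0, length(idx), vocab)
  X[cbind(seq_along(idx), idx)] <- 1
  X
}

## Forward over a padded token matrix (B x Tmax, pad = gap symbol index).
## The model at position t predicts the residue at position t + 1; the
## final position of each sequence trains against the gap symbol. Returns
## the mean token cross-entropy and, if requested, the full cache for BPTT.
lstmForwardBatch <- function(params, tok, lens, hidden, cache = FALSE) {
  vocab <- ncol(params$W_o)
  B <- nrow(tok); Tmax <- max(lens)
  h1 <- matrix(0, B, hidden); c1 <- matrix(0, B, hidden)
  h2 <- matrix(0, B, hidden); c2 <- matrix(0, B, hidden)
  steps <- if (cache) vector("list", Tmax) else NULL
  totalLoss <- 0; totalTok <- 0
  probsList <- if (cache) vector("list", Tmax) else NULL
  for (t in seq_len(Tmax)) {
    active <- lens >= t
    x <- oneHotRows(tok[, t], vocab)
    s1 <- lstmCell(x, h1, c1, params$W1, params$b1, hidden)
    s2 <- lstmCell(s1$h, h2, c2, params$W2, params$b2, hidden)
    h1 <- s1$h; c1 <- s1$c; h2 <- s2$h; c2 <- s2$c
    logits <- sweep(s2$h %*% params$W_o, 2L, params$b_o, "+")
    P <- softmaxRows(logits)
    target <- if (t < ncol(tok)) tok[, t + 1L] else rep(vocab, B)
    target[t >= lens] <- vocab      # end of sequence wraps to the gap symbol
    nll <- -log(clipProb(P[cbind(seq_len(B), target)]))
    totalLoss <- totalLoss + sum(nll[active])
    totalTok <- totalTok + sum(active)
    if (cache) {
      steps[[t]] <- list(s1 = s1, s2 = s2, P = P, target = target,
                         active = active)
    }
  }
  list(loss = totalLoss / totalTok, nTokens = totalTok, steps = steps)
}

## BPTT over a cached forward pass; returns mean-per-token gradients.
lstmBackwardBatch <- function(params, fw, hidden) {
  vocab <- ncol(params$W_o)
  Tmax <- length(fw$steps)
  B <- nrow(fw$steps[[1]]$P)
  g <- zeroLike(params)
  dh1 <- matrix(0, B, hidden); dc1 <- matrix(0, B, hidden)
  dh2 <- matrix(0, B, hidden); dc2 <- matrix(0, B, hidden)
  for (t in rev(seq_len(Tmax))) {
    st <- fw$steps[[t]]
    dlogits <- st$P
    dlogits[cbind(seq_len(B), st$target)] <-
      dlogits[cbind(seq_len(B), st$target)] - 1
    dlogits[!st$active, ] <- 0
    dlogits <- dlogits / fw$nTokens
    g$W_o <- g$W_o + crossprod(st$s2$h, dlogits)
    g$b_o <- g$b_o + colSums(dlogits)
    dh2t <- dh2 + dlogits %*% t(params$W_o)
    bk2 <- lstmCellBackward(st$s2, dh2t, dc2, params$W2, hidden)
    g$W2 <- g$W2 + bk2$dW; g$b2 <- g$b2 + bk2$db
    dh2 <- bk2$dhprev; dc2 <- bk2$dcprev
    dh1t <- dh1 + bk2$dx
    bk1 <- lstmCellBackward(st$s1, dh1t, dc1, params$W1, hidden)
    g$W1 <- g$W1 + bk1$dW; g$b1 <- g$b1 + bk1$db
    dh1 <- bk1$dhprev; dc1 <- bk1$dcprev
  }
  g
}

lstmCellBackward <- function(s, dh, dc, W, h) {
  do <- dh * s$tc
  dcc <- dh * s$o * (1 - s$tc^2) + dc
  di <- dcc * s$g
  df <- dcc * s$cprev
  dg <- dcc * s$i
  dcprev <- dcc * s$f
  dz <- cbind(di * s$i * (1 - s$i),
              df * s$f * (1 - s$f),
              dg * (1 - s$g^2),
              do * s$o * (1 - s$o))
  inp <- cbind(s$x, s$hprev)
  dinp <- dz %*% t(W)
  nin <- ncol(s$x)
  list(dW = crossprod(inp, dz), db = colSums(dz),
       dx = dinp[, seq_len(nin), drop = FALSE],
       dhprev = dinp[, (nin + 1):ncol(dinp), drop = FALSE],
       dcprev = dcprev)
}

padTokens <- function(seqs) {
  toks <- lapply(seqs, tokenize)
  lens <- lengths(toks)
  Tmax <- max(lens)
  tok <- matrix(26L, length(toks), Tmax)
  for (i in seq_along(toks)) tok[i, seq_len(lens[i])] <- toks[[i]]
  list(tok = tok, lens = lens)
}

#' Train the LSTM residue language model
#'
#' Trains a 2-layer forward LSTM next-residue predictor on a sequence
#' corpus with ADAM (learning rate 0.001, batch size 128, 5 epochs by
#' default), holding out a fraction of sequences to monitor the held-out
#' cross-entropy. Deterministic given `seed`. The returned model is used
#' downstream only as a frozen feature extractor.
#'
#' @param sequences Character vector of residue strings (or an
#'   `AAStringSet`).
#' @param hidden Hidden width of each LSTM layer (desk default 64; the
#'   full-scale architecture uses 512).
#' @param epochs,lr,batch_size Optimisation settings.
#' @param seed Integer seed.
#' @param validation_fraction Held-out fraction of sequences.
#' @param verbose Print per-epoch cross-entropies.
#' @return A [LanguageModel-class] with a training log in `config`.
#' @export
trainLanguageModel <- function(sequences, hidden = 64L, epochs = 5L,
                               lr = 0.001, batch_size = 128L, seed = 1L,
                               validation_fraction = 0.1, verbose = FALSE) {
  if (!is.character(sequences)) sequences <- as.character(sequences)
  if (!length(sequences)) stop("empty sequence corpus")
  n <- length(sequences)
  if (n < 2L) stop("corpus must contain at least 2 sequences")
  withr::with_seed(as.integer(seed), {
    params <- lstmInitParams(hidden)
    nVal <- max(1L, round(validation_fraction * n))
    valIdx <- sort(sample.int(n, nVal))
    trIdx <- setdiff(seq_len(n), valIdx)
    valPad <- padTokens(sequences[valIdx])
    opt <- adamInit(params)
    log <- data.frame(epoch = integer(0), train_ce = numeric(0),
                      val_ce = numeric(0))
    for (epoch in seq_len(epochs)) {
      ord <- sample(trIdx)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      ceSum <- 0; ceN <- 0
      for (b in batches) {
        pad <- padTokens(sequences[b])
        fw <- lstmForwardBatch(params, pad$tok, pad$lens, hidden,
                               cache = TRUE)
        g <- lstmBackwardBatch(params, fw, hidden)
        upd <- adamStep(params, g, opt, lr, 0.9, 0.999)
        params <- upd$params; opt <- upd$state
        ceSum <- ceSum + fw$loss * fw$nTokens; ceN <- ceN + fw$nTokens
      }
      valCE <- lstmForwardBatch(params, valPad$tok, valPad$lens,
                                hidden)$loss
      log[nrow(log) + 1L, ] <- list(epoch, ceSum / ceN, valCE)
      if (verbose)
        message(sprintf("LM epoch %d  train CE %.4f  val CE %.4f",
                        epoch, ceSum / ceN, valCE))
    }
    new("LanguageModel", params = params, hiddenSize = hidden,
        config = list(epochs = epochs, lr = lr, batch_size = batch_size,
                      seed = seed, log = log))
  })
}

#' Held-out perplexity of a language model
#'
#' @param lm A [LanguageModel-class] (trained or freshly initialised).
#' @param sequences Character vector of residue strings.
#' @return exp(mean per-token cross-entropy).
#' @export
lmPerplexity <- function(lm, sequences) {
  if (!is.character(sequences)) sequences <- as.character(sequences)
  pad <- padTokens(sequences)
  exp(lstmForwardBatch(lm@params, pad$tok, pad$lens, lm@hiddenSize)$loss)
}

#' Initialise an untrained language model
#'
#' @param hidden Hidden width.
#' @param seed Integer seed.
#' @return A [LanguageModel-class] at random initialisation.
#' @export
initLanguageModel <- function(hidden = 64L, seed = 1L) {
  params <- withr::with_seed(as.integer(seed), lstmInitParams(hidden))
  new("LanguageModel", params = params, hiddenSize = hidden,
      config = list(epochs = 0L, seed = seed))
}

#' Extract frozen per-residue language-model features
#'
#' Runs the forward LSTM over one sequence and returns the top layer's
#' hidden state after consuming residues 1..i in row i. Causality implies
#' a prefix property: features of the first k rows equal the features of
#' the length-k prefix.
#'
#' @param lm A [LanguageModel-class].
#' @param sequence Residue string.
#' @return L x d matrix with entries in (-1, 1).
#' @export
extractLMFeatures <- function(lm, sequence) {
  params <- lm@params
  h <- lm@hiddenSize
  idx <- tokenize(sequence)
  L <- length(idx)
  h1 <- matrix(0, 1, h); c1 <- matrix(0, 1, h)
  h2 <- matrix(0, 1, h); c2 <- matrix(0, 1, h)
  out <- matrix(0, L, h)
  for (t in seq_len(L)) {
    x <- oneHotRows(idx[t], ncol(params$W_o))
    s1 <- lstmCell(x, h1, c1, params$W1, params$b1, h)
    s2 <- lstmCell(s1$h, h2, c2, params$W2, params$b2, h)
    h1 <- s1$h; c1 <- s1$c; h2 <- s2$h; c2 <- s2$c
    out[t, ] <- s2$h
  }
  out
}
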
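## Independent brute-force oracles used across the suite. These are kept
## deliberately naive (O(n^2) scans, exhaustive sweeps, pair counting) and
## never call the implementation paths they check.

## all-pairs Euclidean distances by explicit double loop
bruteDistMatrix <- function(xyz) {
  L <- nrow(xyz)
  D <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in seq_len(L))
    D[i, j] <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  D
}

## full geometry contract of a bead chain: exact bonds, steric floor
checkChainGeometry <- function(xyz, bondTol = 0.01) {
  D <- bruteDistMatrix(xyz)
  L <- nrow(D)
  bonds <- D[cbind(seq_len(L - 1), seq(2, L))]
  sep <- abs(row(D) - col(D))
  list(bond_ok = all(abs(bonds - 3.8) <= bondTol),
       steric_ok = all(D[sep > 1] >= 4.0),
       min_nonadj = min(D[sep > 1]))
}

## CAFA-style Fmax by exhaustive per-threshold recomputation
fmaxOracle <- function(scores, labels, thresholds = seq(0.01, 1, 0.01)) {
  best <- 0
  for (t in thresholds) {
    prs <- c(); rcs <- c()
    for (i in seq_len(nrow(scores))) {
      pred <- which(scores[i, ] >= t)
      pos <- which(labels[i, ] == 1)
      if (length(pred))
        prs <- c(prs, length(intersect(pred, pos)) / length(pred))
      if (length(pos))
        rcs <- c(rcs, length(intersect(pred, pos)) / length(pos))
    }
    pr <- if (length(prs)) mean(prs) else 0
    rc <- mean(rcs)
    f <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    best <- max(best, f)
  }
  best
}

## non-interpolated AUPR by explicit enumeration of distinct thresholds
auprOracle <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  nPos <- sum(labels == 1)
  prevRecall <- 0
  area <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    precision <- tp / sum(pred)
    recall <- tp / nPos
    area <- area + precision * (recall - prevRecall)
    prevRecall <- recall
  }
  area
}

## Mann-Whitney AUROC by pair counting with half-credit ties
aurocPairOracle <- function(x, y) {
  pos <- x[y == 1]; neg <- x[y == 0]
  wins <- 0
  for (p in pos) for (n in neg)
    wins <- wins + (p > n) + 0.5 * (p == n)
  wins / (length(pos) * length(neg))
}

## central finite differences of f over selected coordinates of v0
finiteDiff <- function(f, v0, idx, h = 1e-5) {
  vapply(idx, function(i) {
    e <- v0; e[i] <- e[i] + h; fp <- f(e)
    e[i] <- v0[i] - h
    (fp - f(e)) / (2 * h)
  }, numeric(1))
}

## brute-force transitive closure of a child->parent edge list by repeated
## boolean matrix multiplication
bruteAncestors <- function(edges, terms) {
  n <- length(terms)
  M <- matrix(FALSE, n, n, dimnames = list(terms, terms))
  for (r in seq_len(nrow(edges))) M[edges[r, 1], edges[r, 2]] <- TRUE
  repeat {
    M2 <- M | ((M %*% M) > 0)
    if (identical(M2, M)) break
    M <- M2
  }
  M
}

## tiny deterministic GCN fixture shared by the equation-oracle tests
## the default seed is chosen so that no ReLU pre-activation sits near its
## kink for the fixture sizes used in the suite (finite differences are
## only valid away from kinks)
tinyGCNFixture <- function(L = 7, n_terms = 2, seed = 45, useLM = TRUE) {
  cfg <- gcnConfig(n_layers = 3, channels = 4, c0 = 5, fc_hidden = 6,
                   useLM = useLM, lm_dim = if (useLM) 3 else 0)
  params <- initGCNParams(cfg, n_terms, seed = seed)
  ## keep head logits moderate so softmax outputs stay away from the
  ## clipping boundary (finite differences are exact only there)
  params$W_out <- params$W_out * 0.2
  withr::with_seed(seed + 1, {
    A <- matrix(0, L, L)
    for (i in seq_len(L - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
    A[1, min(5, L)] <- A[min(5, L), 1] <- 1
    feat <- list(
      Ahat = normalizeAdjacency(A),
      X = oneHotEncode(paste(sample(c("A", "C", "D"), L, TRUE),
                             collapse = "")),
      HLM = if (useLM) matrix(rnorm(L * 3), L, 3) else NULL)
    y <- matrix(0, n_terms, 2)
    y[, 1] <- rep_len(c(1, 0), n_terms)
    y[, 2] <- 1 - y[, 1]
    w <- seq(2, 1, length.out = n_terms)
    list(cfg = cfg, params = params, feat = feat, y = y, w = w, A = A)
  })
}
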
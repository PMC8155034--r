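test_that("normalizeAdjacency matches hand-computed values", {
  expect_equal(normalizeAdjacency(matrix(0, 1, 1)), matrix(1, 1, 1))
  expect_equal(normalizeAdjacency(matrix(c(0, 1, 1, 0), 2)),
               matrix(0.5, 2, 2))
  ## 3-node path: degrees with self-loops are (2, 3, 2)
  P <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  Ah <- normalizeAdjacency(P)
  expect_equal(Ah[1, 2], 1 / sqrt(6), tolerance = 1e-12)
  expect_equal(Ah[1, 1], 0.5, tolerance = 1e-12)
  expect_equal(Ah[2, 2], 1 / 3, tolerance = 1e-12)
  expect_error(normalizeAdjacency(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("the largest eigenvalue of the normalized adjacency is exactly 1", {
  withr::with_seed(12, {
    for (rep in 1:5) {
      L <- sample(5:15, 1)
      A <- matrix(rbinom(L * L, 1, 0.3), L, L)
      A[lower.tri(A)] <- t(A)[lower.tri(A)]
      diag(A) <- 0
      ev <- eigen(normalizeAdjacency(A), symmetric = TRUE,
                  only.values = TRUE)$values
      expect_equal(max(ev), 1, tolerance = 1e-10)
    }
  })
})

test_that("graph convolution equals the dense triple-product oracle", {
  Ahat <- diag(4)
  H <- matrix(c(-1, 2, 0.5, -3, 1, 0, 2, -2), 4, 2)
  expect_equal(graphConvLayer(Ahat, H, diag(2)), pmax(H, 0))
  ## all-negative products collapse to zero
  expect_equal(graphConvLayer(Ahat, abs(H), -diag(2)),
               matrix(0, 4, 2))
  withr::with_seed(13, {
    A <- matrix(0, 5, 5); A[1, 2] <- A[2, 1] <- A[2, 5] <- A[5, 2] <- 1
    Ah <- normalizeAdjacency(A)
    H5 <- matrix(rnorm(15), 5, 3)
    W <- matrix(rnorm(6), 3, 2)
  })
  expect_equal(graphConvLayer(Ah, H5, W), pmax(Ah %*% H5 %*% W, 0),
               tolerance = 1e-10)
  expect_error(graphConvLayer(Ah, H5, matrix(0, 4, 2)), "width")
})

test_that("concatAndPool sums residues and is permutation invariant", {
  H1 <- matrix(1:3, 1); H2 <- matrix(4:5, 1)
  expect_equal(concatAndPool(list(H1, H2)), c(1:3, 4:5))
  expect_equal(concatAndPool(list(matrix(0, 4, 2))), c(0, 0))
  withr::with_seed(14, {
    Ha <- matrix(rnorm(12), 4, 3); Hb <- matrix(rnorm(8), 4, 2)
    perm <- sample(4)
  })
  expect_equal(concatAndPool(list(Ha, Hb)),
               concatAndPool(list(Ha[perm, ], Hb[perm, ])))
  expect_error(concatAndPool(list(Ha, Hb[1:3, ])), "inconsistent")
})

test_that("the classification head is a softmax pair per term", {
  head <- list(W_fc = diag(3), b_fc = rep(0, 3),
               W_out = matrix(0, 3, 4), b_out = rep(0, 4))
  P <- classify(c(1, 2, 3), head)
  expect_equal(unname(P), matrix(0.5, 2, 2))
  withr::with_seed(15, {
    head$W_out <- matrix(rnorm(12), 3, 4)
    head$b_out <- rnorm(4)
    h <- rnorm(3)
  })
  P2 <- classify(h, head)
  expect_equal(unname(rowSums(P2)), c(1, 1), tolerance = 1e-9)
  ## shift invariance: adding a constant to both logits of a term
  shifted <- head
  shifted$b_out[c(1, 3)] <- shifted$b_out[c(1, 3)] + 7  # both logits, term 1
  expect_equal(classify(h, shifted)[1, ], P2[1, ], tolerance = 1e-9)
})

test_that("the weighted cross-entropy matches the printed definition", {
  ## perfect prediction drives the loss to ~0
  yhat <- array(0, c(2, 1, 2)); y <- yhat
  y[1, 1, ] <- c(1, 0); y[2, 1, ] <- c(0, 1)
  yhat[1, 1, ] <- c(1 - 1e-9, 1e-9); yhat[2, 1, ] <- c(1e-9, 1 - 1e-9)
  expect_lt(weightedBceLoss(yhat, y, 2), 1e-5)
  ## hand-computed fixture: N=2, one term, w=2
  yhat[1, 1, ] <- c(0.9, 0.1); yhat[2, 1, ] <- c(0.2, 0.8)
  ref <- -(1 / 2) * (2 * log(0.9) + 2 * log(0.8))
  expect_equal(weightedBceLoss(yhat, y, 2), ref, tolerance = 1e-12)
  expect_equal(ref, 0.3285, tolerance = 1e-4)
  ## linear in the weights
  expect_equal(weightedBceLoss(yhat, y, 4),
               2 * weightedBceLoss(yhat, y, 2), tolerance = 1e-12)
})

test_that("analytic GCN gradients match finite differences", {
  fx <- tinyGCNFixture()
  y <- array(fx$y, c(1, dim(fx$y)))
  g <- strucfun:::gcnBatchGrad(fx$params, list(fx$feat), y, fx$w, fx$cfg)
  v0 <- strucfun:::paramsToVector(fx$params)
  gv <- strucfun:::paramsToVector(g)
  f <- function(v) strucfun:::gcnBatchLoss(
    strucfun:::vectorToParams(v, fx$params), list(fx$feat), y, fx$w, fx$cfg)
  withr::with_seed(5, idx <- sample(length(v0), 50))
  fd <- finiteDiff(f, v0, idx)
  keep <- abs(fd) > 1e-7
  expect_lt(max(abs(fd[keep] - gv[idx][keep]) / abs(fd[keep])), 1e-4)
})

test_that("predictions are invariant to joint residue permutation and padding", {
  fx <- tinyGCNFixture(L = 9)
  fw <- strucfun:::gcnForward(fx$params, fx$feat, fx$cfg)
  withr::with_seed(6, perm <- sample(9))
  permFeat <- list(Ahat = normalizeAdjacency(fx$A[perm, perm]),
                   X = fx$feat$X[perm, ], HLM = fx$feat$HLM[perm, ])
  fwP <- strucfun:::gcnForward(fx$params, permFeat, fx$cfg)
  expect_equal(fwP$probs, fw$probs, tolerance = 1e-6)

  ## appending masked padded residues changes nothing
  Apad <- rbind(cbind(fx$A, matrix(0, 9, 3)), matrix(0, 3, 12))
  padFeat <- list(Ahat = normalizeAdjacency(Apad),
                  X = rbind(fx$feat$X, matrix(0, 3, 26)),
                  HLM = rbind(fx$feat$HLM, matrix(0, 3, 3)),
                  mask = c(rep(TRUE, 9), rep(FALSE, 3)))
  fwPad <- strucfun:::gcnForward(fx$params, padFeat, fx$cfg)
  expect_equal(fwPad$probs, fw$probs, tolerance = 1e-6)
})

test_that("early stopping follows the patience rule and keeps the best epoch", {
  sched <- earlyStopSchedule(c(1.0, 0.9, 0.91, 0.92, 0.93, 0.94, 0.95),
                             patience = 5)
  expect_equal(sched$stop_epoch, 7)
  expect_equal(sched$best_epoch, 2)
  ## monotone improvement never stops early
  sched2 <- earlyStopSchedule(seq(1, 0.1, length.out = 8), patience = 5)
  expect_equal(sched2$stop_epoch, 8)
  expect_equal(sched2$best_epoch, 8)
})

test_that("training overfits a tiny dataset, is seed-deterministic, and predicts calls strictly above 0.5", {
  ds <- generateDataset(syntheticConfig(n_proteins = 10, n_terms = 2,
                                        length_range = c(40L, 50L),
                                        planting_probs = c(0.5, 0.6),
                                        label_noise_rate = 0, seed = 71))
  space <- buildLabelSpace(ds$records)
  cfg <- gcnConfig(n_layers = 2, channels = 8, c0 = 8, fc_hidden = 12,
                   useLM = FALSE)
  m1 <- trainGCN(ds$records, space, cfg, seed = 5, lr = 3e-3,
                 max_epochs = 40, patience = 40)
  log1 <- m1@trainingLog
  expect_lt(tail(log1$train_loss, 1), log1$train_loss[1])
  m2 <- trainGCN(ds$records, space, cfg, seed = 5, lr = 3e-3,
                 max_epochs = 40, patience = 40)
  expect_identical(strucfun:::paramsToVector(m1@params),
                   strucfun:::paramsToVector(m2@params))

  pred <- predictFunctions(m1, ds$records[[1]])
  expect_true(all(pred$score >= 0 & pred$score <= 1))

  ## a zero-parameter model scores exactly 0.5: the call must be negative
  zero <- m1
  zero@params <- lapply(m1@params, function(p) { p[] <- 0; p })
  predZ <- predictFunctions(zero, ds$records[[1]])
  expect_true(all(predZ$score == 0.5))
  expect_false(any(predZ$call))

  ## length guard at prediction time
  tiny <- m1
  tiny@config$max_len <- 10L
  expect_error(predictFunctions(tiny, ds$records[[1]]), "maximum")
})
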
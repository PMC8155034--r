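test_that("one-hot encoding is a proper indicator over the 26-channel vocabulary", {
  X <- oneHotEncode("A")
  expect_equal(dim(X), c(1L, 26L))
  expect_equal(sum(X), 1)
  expect_equal(unname(X[1, "A"]), 1)

  withr::with_seed(2, s <- paste(sample(residueVocabulary(), 40, TRUE),
                                 collapse = ""))
  expect_true(all(rowSums(oneHotEncode(s)) == 1))

  expect_warning(Xx <- oneHotEncode("AXA"), "gap channel")
  expect_equal(unname(Xx[2, "-"]), 1)
  ## non-standard channels map to themselves, not the gap
  expect_equal(unname(oneHotEncode("B")[1, "B"]), 1)
})

test_that("feature fusion computes ReLU(H W_LM + X W_X + b)", {
  withr::with_seed(3, {
    L <- 6
    X <- oneHotEncode(paste(sample(c("A", "C", "G"), L, TRUE), collapse = ""))
    HLM <- matrix(rnorm(L * 4), L, 4)
    params <- initFusionParams(4, 5)
  })
  out <- fuseFeatures(HLM, X, params)
  ## independent dense-product oracle
  Z <- HLM %*% params$W_LM + X %*% params$W_X
  Z <- Z + matrix(params$b, L, 5, byrow = TRUE)
  expect_equal(out, pmax(Z, 0), tolerance = 1e-12)
  expect_true(all(out >= 0))

  ## zero weights: every row is ReLU(b)
  z <- params
  z$W_LM[] <- 0; z$W_X[] <- 0; z$b <- c(-1, 0.5, -0.2, 2, 0)
  outz <- fuseFeatures(HLM, X, z)
  expect_true(all(apply(outz, 1, function(r)
    isTRUE(all.equal(r, pmax(z$b, 0))))))

  ## LM pathway disabled
  noLM <- initFusionParams(0, 5)
  expect_null(noLM$W_LM)
  expect_equal(fuseFeatures(NULL, X, noLM),
               pmax(sweep(X %*% noLM$W_X, 2, noLM$b, "+"), 0))

  expect_error(fuseFeatures(HLM[1:3, ], X, params), "same number")
  expect_error(fuseFeatures(matrix(0, L, 7), X, params), "W_LM expects")
})

test_that("fusion is piecewise linear away from ReLU kinks", {
  withr::with_seed(9, {
    X <- oneHotEncode("ACDE")
    HLM <- matrix(rnorm(16), 4, 4)
    params <- initFusionParams(4, 3)
    dir <- matrix(rnorm(16), 4, 4)
  })
  f <- function(t) fuseFeatures(HLM + t * dir, X, params)
  eps <- 1e-4
  ## central slope at two scales agrees where no unit crosses zero
  s1 <- (f(eps) - f(-eps)) / (2 * eps)
  s2 <- (f(eps / 2) - f(-eps / 2)) / eps
  active <- abs(f(0)) > 1e-3
  expect_equal(s1[active], s2[active], tolerance = 1e-6)
})

test_that("the language model starts at uniform perplexity and improves with training", {
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr::with_seed(4, corpus <- vapply(1:40, function(i)
    paste(sample(aa20, 60, TRUE), collapse = ""), character(1)))
  init <- initLanguageModel(hidden = 16, seed = 1)
  p0 <- lmPerplexity(init, corpus)
  expect_lt(abs(p0 - 26) / 26, 0.1)

  lm <- trainLanguageModel(corpus, hidden = 16, epochs = 2, seed = 6)
  held <- withr::with_seed(5, vapply(1:10, function(i)
    paste(sample(aa20, 60, TRUE), collapse = ""), character(1)))
  expect_lt(lmPerplexity(lm, held), lmPerplexity(init, held))

  lm2 <- trainLanguageModel(corpus, hidden = 16, epochs = 2, seed = 6)
  expect_identical(lm@params, lm2@params)

  expect_error(trainLanguageModel(character(0)), "empty")
})

test_that("LM features are causal, bounded and frozen under downstream use", {
  lm <- initLanguageModel(hidden = 16, seed = 2)
  H <- extractLMFeatures(lm, "ACDEFGHIK")
  expect_equal(dim(H), c(9L, 16L))
  expect_true(all(H > -1 & H < 1))
  ## prefix property of a forward LSTM
  Hpre <- extractLMFeatures(lm, "ACDE")
  expect_identical(H[1:4, ], Hpre)

  ## frozen-LM contract across downstream training
  ds <- generateDataset(syntheticConfig(n_proteins = 8, n_terms = 2,
                                        length_range = c(40L, 50L),
                                        planting_probs = c(0.5, 0.6),
                                        seed = 61))
  space <- buildLabelSpace(ds$records)
  before <- lm@params
  model <- trainGCN(ds$records, space,
                    gcnConfig(n_layers = 2, channels = 6, c0 = 6,
                              fc_hidden = 8, useLM = TRUE, lm_dim = 16),
                    seed = 3, lm = lm, max_epochs = 3)
  expect_identical(model@lm@params, before)
})

test_that("LSTM gradients match central finite differences", {
  params <- strucfun:::lstmInitParams(4)
  pad <- strucfun:::padTokens(c("ACDEFG", "ACD"))
  fw <- strucfun:::lstmForwardBatch(params, pad$tok, pad$lens, 4, cache = TRUE)
  g <- strucfun:::lstmBackwardBatch(params, fw, 4)
  v0 <- strucfun:::paramsToVector(params)
  gv <- strucfun:::paramsToVector(g)
  f <- function(v) strucfun:::lstmForwardBatch(
    strucfun:::vectorToParams(v, params), pad$tok, pad$lens, 4)$loss
  withr::with_seed(7, idx <- sample(length(v0), 30))
  fd <- finiteDiff(f, v0, idx)
  keep <- abs(fd) > 1e-6
  expect_lt(max(abs(fd[keep] - gv[idx][keep]) / abs(fd[keep])), 1e-4)
})
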
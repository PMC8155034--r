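## assemble a GCNModel around fixture parameters so gradCam can run
fixtureModel <- function(fx, n_terms = 2) {
  space <- new("LabelSpace", termIds = paste0("T", seq_len(n_terms)),
               termNames = paste0("T", seq_len(n_terms)),
               counts = rep(5, n_terms), ic = rep(1, n_terms),
               weights = rep(2, n_terms), nProteins = 10)
  new("GCNModel", params = fx$params, config = fx$cfg, labelSpace = space,
      lm = NULL, trainingLog = data.frame())
}

test_that("zero feature maps give an identically zero CAM", {
  fx <- tinyGCNFixture(useLM = FALSE)
  fx$params$Wg3[] <- 0       # final layer output is identically zero
  model <- fixtureModel(fx)
  prof <- gradCam(model, fx$feat, "T1")
  expect_true(all(prof@raw == 0))
  expect_true(all(prof@profile == 0))
  expect_error(gradCam(model, fx$feat, "nope"), "not in the model")
})

test_that("grad-CAM matches the analytic gradient of a linear head", {
  fx <- tinyGCNFixture(useLM = FALSE)
  ## make the head linear in the pooled final-layer features: identity FC
  ## (pooled sums are non-negative so the ReLU is inactive), then a linear
  ## map whose positive-class logit for term 1 has coefficients c_k on the
  ## final layer's channel block
  sumC <- sum(fx$cfg$channels)
  fx$params$W_fc <- diag(sumC)
  fx$params$b_fc <- rep(0, sumC)
  fx$params$W_out <- matrix(0, sumC, 4)
  cvec <- c(0.5, -0.2, 1.0, 0.3)
  lastBlock <- (sumC - 4 + 1):sumC
  fx$params$W_out[lastBlock, 1] <- cvec
  fx$params$b_out <- rep(0, 4)
  model <- fixtureModel(fx)
  prof <- gradCam(model, fx$feat, "T1", on = "logit")
  fw <- strucfun:::gcnForward(fx$params, fx$feat, fx$cfg)
  L <- nrow(fw$H0)
  ## dy/dF_{k,i} = c_k, so w_k = L c_k and CAM = ReLU(F %*% (L c))
  expected <- pmax(drop(fw$Hs[[3]] %*% (L * cvec)), 0)
  expect_equal(prof@raw, expected, tolerance = 1e-9)
})

test_that("saliency gradients match finite differences on the feature maps", {
  fx <- tinyGCNFixture(L = 10, useLM = FALSE)
  model <- fixtureModel(fx)
  fw <- strucfun:::gcnForward(fx$params, fx$feat, fx$cfg)
  mask <- rep(TRUE, 10)
  dh <- strucfun:::gcnPoolGradient(fx$params, fw, 1L, "probability")
  off <- sum(fx$cfg$channels[-3])
  gBlock <- dh[(off + 1):(off + fx$cfg$channels[3])]
  ## independent path: perturb entries of the final layer's feature map and
  ## recompute the head output
  f <- function(Hmod) strucfun:::gcnHeadFromLayers(
    fx$params, list(fw$Hs[[1]], fw$Hs[[2]], Hmod), mask, 1L, "probability")
  h <- 1e-5
  for (k in seq_len(fx$cfg$channels[3])) {
    for (i in c(1, 5, 10)) {
      Hp <- fw$Hs[[3]]; Hp[i, k] <- Hp[i, k] + h
      Hm <- fw$Hs[[3]]; Hm[i, k] <- Hm[i, k] - h
      fd <- (f(Hp) - f(Hm)) / (2 * h)
      if (abs(fd) > 1e-8)
        expect_lt(abs(fd - gBlock[k]) / abs(fd), 1e-4)
    }
  }
})

test_that("CAM on the positive logit ignores shifts of the negative-class logit", {
  fx <- tinyGCNFixture(useLM = FALSE)
  model <- fixtureModel(fx)
  base <- gradCam(model, fx$feat, "T1", on = "logit")
  shifted <- fx
  Tn <- 2
  shifted$params$b_out[Tn + 1] <- shifted$params$b_out[Tn + 1] + 5
  model2 <- fixtureModel(shifted)
  expect_equal(gradCam(model2, fx$feat, "T1", on = "logit")@raw, base@raw,
               tolerance = 1e-10)
  ## on the probability the raw map rescales but the normalized profile
  ## is unchanged
  pb <- gradCam(model, fx$feat, "T1")
  pb2 <- gradCam(model2, fx$feat, "T1")
  expect_equal(pb2@profile, pb@profile, tolerance = 1e-8)
})

test_that("saliency evaluation aggregates per-pair AUROCs and detects shuffles", {
  ds <- generateDataset(syntheticConfig(n_proteins = 16, n_terms = 2,
                                        length_range = c(50L, 60L),
                                        planting_probs = c(0.6, 0.7),
                                        label_noise_rate = 0, seed = 81))
  space <- buildLabelSpace(ds$records)
  model <- trainGCN(ds$records, space,
                    gcnConfig(n_layers = 2, channels = 8, c0 = 8,
                              fc_hidden = 12, useLM = FALSE),
                    seed = 4, lr = 3e-3, max_epochs = 25, patience = 25)
  ev <- evaluateSaliency(model, ds$records)
  expect_gt(nrow(ev$table), 0)
  expect_true(all(ev$table$auroc >= 0 & ev$table$auroc <= 1))

  ## a suite of one protein aggregates to that protein's AUROC
  one <- ds$records[[which(vapply(ds$records, function(r)
    length(r@motifIndices) == 1, logical(1)))[1]]]
  evOne <- evaluateSaliency(model, list(one))
  expect_equal(evOne$aggregate_auroc, evOne$table$auroc[1])

  ## shuffling site profiles across proteins collapses the signal to chance
  withr::with_seed(9, shuffled <- lapply(ds$records, function(r) {
    sites <- lapply(r@motifIndices, function(idx)
      sample(nchar(r@sequence), length(idx)))
    sites
  }))
  names(shuffled) <- vapply(ds$records, proteinId, character(1))
  evShuf <- evaluateSaliency(model, ds$records, sites = shuffled)
  expect_lt(abs(evShuf$mean_auroc - 0.5), 0.2)
  expect_lt(evShuf$mean_auroc, ev$mean_auroc)
})

test_that("site profiles round-trip through the TSV reader", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("P1\tGO:1\t0,4,9", "P1\tGO:2\t2", "P2\tGO:1\t1,3"), f)
  sp <- readSiteProfiles(f)
  expect_identical(sp$P1[["GO:1"]], c(1L, 5L, 10L))
  expect_identical(sp$P2[["GO:1"]], c(2L, 4L))
})
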
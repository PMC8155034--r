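#' @include AllClasses.R synthetic.R gcn.R cnn.R lstm.R gradcam.R metrics.R
NULL

#' Save / load a trained model
#'
#' Models serialize bit-exactly through R's native serialization; a JSON
#' sidecar records the architecture manifest (layer widths, vocabulary
#' order, label space) for reproducibility across sessions.
#'
#' @param model A [GCNModel-class], [CNNModel-class] or
#'   [LanguageModel-class].
#' @param path Checkpoint path (`.rds`); the manifest is written next to it.
#' @return `loadModel` returns the model object.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  manifest <- list(class = class(model)[1],
                   package_version = as.character(packageVersion("strucfun")),
                   vocabulary = residueVocabulary())
  if (is(model, "GCNModel") || is(model, "CNNModel")) {
    manifest$config <- model@config[setdiff(names(model@config), "layer_fun")]
    manifest$term_ids <- model@labelSpace@termIds
  }
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) readRDS(path)

#' Read an annotation TSV
#'
#' Three tab-separated columns with a header: `protein_id`, `term_id`,
#' `evidence`.
#'
#' @param path Input path.
#' @return Data frame.
#' @export
readAnnotations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "term_id")
  if (!all(need %in% names(df)))
    stop("annotation table needs columns protein_id and term_id")
  df
}

pipelineDefaults <- function() {
  list(seed = 1L, n_train = 300L, n_test = 60L,
       length_range = c(60L, 120L), n_terms = 6L,
       label_noise_rate = 0.05, use_lm = TRUE, lm_hidden = 32L,
       lm_epochs = 3L, gcn_channels = 32L, gcn_fc_hidden = 64L,
       lr = 3e-3, max_epochs = 120L, patience = 5L, batch_size = 32L,
       n_bootstrap = 20L)
}

#' Run the synthetic end-to-end pipeline
#'
#' Wires the stages in dependency order: simulate a planted-motif dataset,
#' build contact maps, train the language model, train the GCN, score the
#' held-out proteins, compute grad-CAM saliency for planted sites, and
#' evaluate (Fmax, macro AUPR, bootstrap summary, saliency AUROC). Writes
#' the dataset, predictions, saliency and evaluation report plus a run
#' manifest into `outDir`. All randomness derives from the single root
#' seed, so a rerun with the same config reproduces the outputs.
#'
#' @param config Path to a JSON config file, or a named list; unknown keys
#'   are an error. See `pipelineDefaults` in the package sources for the
#'   recognised keys and defaults.
#' @param outDir Output directory.
#' @return Invisibly, a list with the dataset, models and evaluation.
#' @export
runPipeline <- function(config = list(), outDir) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  defaults <- pipelineDefaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  tic <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    out
  }

  scfg <- syntheticConfig(n_proteins = cfg$n_train + cfg$n_test,
                          length_range = cfg$length_range,
                          n_terms = cfg$n_terms,
                          label_noise_rate = cfg$label_noise_rate,
                          seed = deriveSeed(cfg$seed, "simulate"))
  ds <- tic("simulate", generateDataset(scfg))
  tic("write_dataset", writeDataset(ds, file.path(outDir, "dataset")))
  trainRec <- ds$records[seq_len(cfg$n_train)]
  testRec <- ds$records[cfg$n_train + seq_len(cfg$n_test)]
  space <- buildLabelSpace(trainRec, ds$labelSpace@termIds)

  lm <- NULL
  if (cfg$use_lm) {
    lm <- tic("train_lm", trainLanguageModel(
      vapply(trainRec, function(r) r@sequence, character(1)),
      hidden = cfg$lm_hidden, epochs = cfg$lm_epochs,
      seed = deriveSeed(cfg$seed, "lm")))
    saveModel(lm, file.path(outDir, "lm.rds"))
  }

  gcnCfg <- gcnConfig(channels = cfg$gcn_channels,
                      fc_hidden = cfg$gcn_fc_hidden,
                      useLM = cfg$use_lm, lm_dim = cfg$lm_hidden)
  model <- tic("train", trainGCN(trainRec, space, gcnCfg,
                                 seed = deriveSeed(cfg$seed, "train"),
                                 lm = lm, lr = cfg$lr,
                                 max_epochs = cfg$max_epochs,
                                 patience = cfg$patience,
                                 batch_size = cfg$batch_size))
  saveModel(model, file.path(outDir, "gcn.rds"))

  scores <- tic("predict", scoreProteins(model, testRec))
  writePredictionTable(scores, space, file.path(outDir, "predictions.tsv"))

  sal <- tic("explain", evaluateSaliency(model, testRec))
  profiles <- list()
  for (r in testRec) {
    for (t in names(r@motifIndices)) {
      if (t %in% space@termIds)
        profiles[[length(profiles) + 1L]] <- gradCam(model, r, t)
    }
  }
  if (length(profiles))
    writeSaliency(profiles, file.path(outDir, "saliency.json"),
                  file.path(outDir, "saliency.tsv"))

  yTrue <- labelMatrix(testRec, space, truth = TRUE)
  fm <- fmax(scores, yTrue)
  au <- macroAupr(scores, yTrue)
  boot <- bootstrapMetric(function(s, y) fmax(s, y)$fmax, scores, yTrue,
                          n_boot = cfg$n_bootstrap,
                          seed = deriveSeed(cfg$seed, "bootstrap"))
  evaluation <- list(
    fmax = fm$fmax, fmax_threshold = fm$threshold,
    macro_aupr = au$macro, per_term_aupr = as.list(au$per_term),
    fmax_bootstrap = boot[c("mean", "sd", "median", "q25", "q75")],
    saliency_mean_auroc = sal$mean_auroc,
    saliency_aggregate_auroc = sal$aggregate_auroc,
    mean_test_prevalence = mean(colMeans(yTrue)))
  jsonlite::write_json(evaluation, file.path(outDir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(config = cfg,
                   derived_seeds = list(
                     simulate = deriveSeed(cfg$seed, "simulate"),
                     lm = deriveSeed(cfg$seed, "lm"),
                     train = deriveSeed(cfg$seed, "train"),
                     bootstrap = deriveSeed(cfg$seed, "bootstrap")),
                   package_version =
                     as.character(packageVersion("strucfun")),
                   input_hashes = as.list(tools::md5sum(
                     file.path(outDir, "dataset",
                               c("sequences.fasta", "labels.tsv")))),
                   timings = timings)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dataset = ds, train = trainRec, test = testRec,
                 labelSpace = space, lm = lm, model = model,
                 scores = scores, evaluation = evaluation))
}

#' Build a label space from training records
#'
#' Counts positive observed labels on the training partition only and
#' derives information content and class weights from those counts.
#'
#' @param records Training [ProteinRecord-class] list.
#' @param termIds Term identifiers to include (default: all seen).
#' @return A [LabelSpace-class].
#' @export
buildLabelSpace <- function(records, termIds = NULL) {
  lab <- do.call(rbind, lapply(records, function(r) r@labels))
  if (is.null(termIds)) termIds <- sort(colnames(lab))
  counts <- colSums(lab[, termIds, drop = FALSE])
  if (any(counts == 0))
    stop("term(s) without positive training examples: ",
         paste(termIds[counts == 0], collapse = ", "))
  N <- nrow(lab)
  new("LabelSpace", termIds = termIds, termNames = termIds,
      counts = as.numeric(counts), ic = informationContent(counts / N),
      weights = N / as.numeric(counts), nProteins = N)
}
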
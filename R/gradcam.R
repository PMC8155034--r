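#' @include AllClasses.R utils.R gcn.R metrics.R
NULL

## Gradient of the model output for one term with respect to the pooled
## representation; `on` selects the positive-class probability (default)
## or the raw positive logit.
gcnPoolGradient <- function(params, fw, termIdx, on = "probability") {
  Tn <- nrow(fw$probs)
  dlogits <- numeric(2L * Tn)
  if (on == "probability") {
    p1 <- fw$probs[termIdx, 1]; p2 <- fw$probs[termIdx, 2]
    dlogits[termIdx] <- p1 * (1 - p1)
    dlogits[Tn + termIdx] <- -p1 * p2
  } else {
    dlogits[termIdx] <- 1
  }
  dh1 <- drop(params$W_out %*% dlogits)
  da1 <- dh1 * (fw$a1 > 0)
  drop(params$W_fc %*% da1)
}

## Output of the classification head for one term when the graph-layer
## outputs are supplied directly; the independent path used by the
## finite-difference saliency checks.
gcnHeadFromLayers <- function(params, Hlist, mask, termIdx,
                              on = "probability") {
  hpool <- concatAndPool(Hlist, mask)
  P <- classify(hpool, list(W_fc = params$W_fc, b_fc = params$b_fc,
                            W_out = params$W_out, b_out = params$b_out))
  if (on == "probability") P[termIdx, 1] else {
    a1 <- relu(drop(hpool %*% params$W_fc) + params$b_fc)
    (drop(a1 %*% params$W_out) + params$b_out)[termIdx]
  }
}

#' Grad-CAM residue saliency for one (protein, term) pair
#'
#' Computes the gradient-weighted class activation map of the positive
#' output for `term` with respect to the feature maps of the final graph
#' convolution layer: channel importances are the gradients summed over
#' residues, `w_k = sum_i dy/dF_ki`, and the map is
#' `CAM[i] = ReLU(sum_k w_k F_ki)`, keeping only channels with positive
#' influence. The normalized profile divides by the maximum (an all-zero
#' map stays all-zero). Padded residues are excluded from both the channel
#' sums and the profile.
#'
#' @param model A trained [GCNModel-class].
#' @param protein A [ProteinRecord-class] (or prebuilt feature list).
#' @param term Term identifier, must be in the model's label space.
#' @param source Feature-map source: the final graph layer (default) or
#'   the concatenation of all layers.
#' @param on Differentiate the positive-class probability (default) or the
#'   raw positive logit.
#' @return A [SaliencyProfile-class].
#' @export
gradCam <- function(model, protein, term,
                    source = c("last_layer", "concat"),
                    on = c("probability", "logit")) {
  source <- match.arg(source); on <- match.arg(on)
  termIdx <- match(term, model@labelSpace@termIds)
  if (is.na(termIdx))
    stop(sprintf("term %s is not in the model's label space", term))
  pid <- if (is(protein, "ProteinRecord")) protein@id else "protein"
  feat <- if (is(protein, "ProteinRecord"))
    featurizeRecords(list(protein), model@lm)[[1]] else protein
  cfg <- model@config
  fw <- gcnForward(model@params, feat, cfg)
  dhpool <- gcnPoolGradient(model@params, fw, termIdx, on)
  if (any(!is.finite(dhpool))) stop("non-finite saliency gradients")
  Lvalid <- sum(fw$mask)
  if (source == "last_layer") {
    off <- sum(cfg$channels[-cfg$n_layers])
    g <- dhpool[(off + 1L):(off + cfg$channels[cfg$n_layers])]
    Fmap <- fw$Hs[[cfg$n_layers]]
  } else {
    g <- dhpool
    Fmap <- do.call(cbind, fw$Hs)
  }
  wk <- Lvalid * g
  cam <- relu(drop(Fmap %*% wk))
  cam[!fw$mask] <- 0
  profile <- if (max(cam) > 0) cam / max(cam) else cam
  new("SaliencyProfile", proteinId = pid, termId = term,
      raw = cam, profile = profile,
      layer = if (source == "last_layer")
        sprintf("graph_conv_%d", cfg$n_layers) else "concat")
}

#' Evaluate grad-CAM profiles against known site profiles
#'
#' For each (protein, term) pair with a site profile, computes the
#' residue-level AUROC between the normalized grad-CAM profile and the
#' binary site vector; also pools all (saliency, site) residue pairs
#' across proteins into one aggregate AUROC. Pairs with degenerate site
#' profiles (no positive or no negative residue) are skipped and counted.
#'
#' @param model A trained [GCNModel-class].
#' @param records List of [ProteinRecord-class] objects.
#' @param sites Named list: `sites[[protein_id]][[term_id]]` is a vector of
#'   1-based site residue indices. When `NULL`, the records' planted
#'   `motifIndices` are used.
#' @param onlyPredicted Restrict to pairs the model calls positive
#'   (score > 0.5).
#' @return List with `table` (per-pair AUROC rows), `mean_auroc`,
#'   `median_auroc`, `aggregate_auroc`, `n_skipped`.
#' @export
evaluateSaliency <- function(model, records, sites = NULL,
                             onlyPredicted = FALSE) {
  rows <- list(); pooledS <- numeric(0); pooledY <- numeric(0)
  skipped <- 0L
  for (r in records) {
    siteMap <- if (is.null(sites)) r@motifIndices else sites[[r@id]]
    if (is.null(siteMap) || !length(siteMap)) next
    pred <- if (onlyPredicted) predictFunctions(model, r) else NULL
    for (term in names(siteMap)) {
      if (!term %in% model@labelSpace@termIds) next
      if (onlyPredicted && !isTRUE(pred$call[pred$term_id == term])) next
      L <- nchar(r@sequence)
      s <- numeric(L)
      s[siteMap[[term]]] <- 1
      if (sum(s) == 0 || sum(s) == L) { skipped <- skipped + 1L; next }
      prof <- gradCam(model, r, term)@profile
      auc <- residueAuroc(prof, s)
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = r@id, term_id = term, auroc = auc, n_site = sum(s),
        stringsAsFactors = FALSE)
      pooledS <- c(pooledS, prof); pooledY <- c(pooledY, s)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(0), term_id = character(0),
               auroc = numeric(0), n_site = numeric(0))
  list(table = tab,
       mean_auroc = if (nrow(tab)) mean(tab$auroc) else NA_real_,
       median_auroc = if (nrow(tab)) median(tab$auroc) else NA_real_,
       aggregate_auroc = if (length(pooledS) &&
                             any(pooledY == 1) && any(pooledY == 0))
         residueAuroc(pooledS, pooledY) else NA_real_,
       n_skipped = skipped)
}

#' Read site profiles from a BioLiP/CSA-style TSV
#'
#' Three tab-separated columns: protein id, function id, comma-separated
#' 0-based residue indices.
#'
#' @param path Input TSV path.
#' @return Named list keyed by protein id, each a named list of 1-based
#'   index vectors keyed by term id.
#' @export
readSiteProfiles <- function(path) {
  df <- read.delim(path, header = FALSE,
                   col.names = c("protein_id", "term_id", "residues"),
                   stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(df))) {
    idx <- as.integer(strsplit(df$residues[i], ",")[[1]]) + 1L
    out[[df$protein_id[i]]][[df$term_id[i]]] <- idx
  }
  out
}

#' Write saliency profiles as JSON and TSV
#'
#' The JSON maps protein id to term id to the per-residue scores
#' (0-based residue order); the TSV has one row per residue.
#'
#' @param profiles List of [SaliencyProfile-class] objects.
#' @param jsonPath,tsvPath Output paths (either may be `NULL`).
#' @export
writeSaliency <- function(profiles, jsonPath = NULL, tsvPath = NULL) {
  if (!is.null(jsonPath)) {
    j <- list()
    for (p in profiles) j[[p@proteinId]][[p@termId]] <- p@profile
    jsonlite::write_json(j, jsonPath, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsvPath)) {
    df <- do.call(rbind, lapply(profiles, function(p)
      data.frame(protein_id = p@proteinId, term_id = p@termId,
                 residue_index = seq_along(p@profile) - 1L,
                 score = p@profile)))
    write.table(df, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}
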
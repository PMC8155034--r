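#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' Accessor generics for the central data objects: the adjacency matrix,
#' mode and threshold of a [ContactMap-class]; term identifiers, counts,
#' information content and class weights of a [LabelSpace-class].
#'
#' @param x An object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setGeneric("contactMode", function(x) standardGeneric("contactMode"))
#' @rdname accessors
#' @export
setGeneric("contactThreshold", function(x) standardGeneric("contactThreshold"))
#' @rdname accessors
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))
#' @rdname accessors
#' @export
setGeneric("termCounts", function(x) standardGeneric("termCounts"))
#' @rdname accessors
#' @export
setGeneric("classWeights", function(x) standardGeneric("classWeights"))
#' @rdname accessors
#' @export
setGeneric("infoContent", function(x) standardGeneric("infoContent"))
#' @rdname accessors
#' @export
setGeneric("proteinId", function(x) standardGeneric("proteinId"))
#' @rdname accessors
#' @export
setGeneric("residueSequence", function(x) standardGeneric("residueSequence"))
#' @rdname accessors
#' @export
setGeneric("coordinates", function(x) standardGeneric("coordinates"))
#' @rdname accessors
#' @export
setGeneric("contactMap", function(x) standardGeneric("contactMap"))
#' @rdname accessors
#' @export
setGeneric("saliency", function(x) standardGeneric("saliency"))

#' @rdname accessors
#' @export
setMethod("adjacency", "ContactMap", function(x) x@adjacency)
#' @rdname accessors
#' @export
setMethod("contactMode", "ContactMap", function(x) x@mode)
#' @rdname accessors
#' @export
setMethod("contactThreshold", "ContactMap", function(x) x@threshold)

#' @rdname accessors
#' @export
setMethod("termIds", "LabelSpace", function(x) x@termIds)
#' @rdname accessors
#' @export
setMethod("termCounts", "LabelSpace",
          function(x) setNames(x@counts, x@termIds))
#' @rdname accessors
#' @export
setMethod("classWeights", "LabelSpace",
          function(x) setNames(x@weights, x@termIds))
#' @rdname accessors
#' @export
setMethod("infoContent", "LabelSpace",
          function(x) setNames(x@ic, x@termIds))

#' @rdname accessors
#' @export
setMethod("proteinId", "ProteinRecord", function(x) x@id)
#' @rdname accessors
#' @export
setMethod("residueSequence", "ProteinRecord", function(x) x@sequence)
#' @rdname accessors
#' @export
setMethod("coordinates", "ProteinRecord", function(x) x@coords)
#' @rdname accessors
#' @export
setMethod("contactMap", "ProteinRecord", function(x) x@cmap)

#' @rdname accessors
#' @export
setMethod("saliency", "SaliencyProfile", function(x) x@profile)

#' @describeIn accessors Number of residues in a record.
#' @export
setMethod("length", "ProteinRecord", function(x) nchar(x@sequence))
#' @describeIn accessors Number of terms in a label space.
#' @export
setMethod("length", "LabelSpace", function(x) length(x@termIds))

setMethod("show", "ContactMap", function(object) {
  A <- object@adjacency
  cat(sprintf("ContactMap: %d residues, mode %s%s, %d contacts (density %.3f)\n",
              nrow(A), object@mode,
              if (is.na(object@threshold)) "" else
                sprintf(" (< %g A)", object@threshold),
              sum(A) / 2,
              if (nrow(A) > 1) sum(A) / (nrow(A) * (nrow(A) - 1)) else 0))
})

setMethod("show", "ProteinRecord", function(object) {
  cat(sprintf("ProteinRecord %s: %d residues%s%s\n", object@id,
              nchar(object@sequence),
              if (is.null(object@coords)) "" else ", with coordinates",
              if (is.null(object@cmap)) "" else ", with contact map"))
  if (length(object@labels))
    cat(sprintf("  labels: %d positive of %d terms\n",
                sum(object@labels), length(object@labels)))
})

setMethod("show", "LabelSpace", function(object) {
  cat(sprintf("LabelSpace: %d terms over %d proteins\n",
              length(object@termIds), object@nProteins))
  k <- min(5L, length(object@termIds))
  for (i in seq_len(k)) {
    cat(sprintf("  %s  N+=%d  IC=%.2f  w=%.2f\n", object@termIds[i],
                as.integer(object@counts[i]), object@ic[i],
                object@weights[i]))
  }
  if (length(object@termIds) > k) cat("  ...\n")
})

setMethod("show", "LanguageModel", function(object) {
  cat(sprintf(
    "LanguageModel: 2-layer forward LSTM, hidden %d, vocab %d (frozen)\n",
    object@hiddenSize, ncol(object@params$W_o)))
})

setMethod("show", "GCNModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "GCNModel: %d graph conv layers (%s channels), FC %d, %d terms%s\n",
    cfg$n_layers, paste(cfg$channels, collapse = "/"), cfg$fc_hidden,
    length(object@labelSpace@termIds),
    if (is.null(object@lm)) ", one-hot features" else
      ", LSTM-LM + one-hot features"))
  if (nrow(object@trainingLog))
    cat(sprintf("  trained %d epochs, best val loss %.4f\n",
                nrow(object@trainingLog),
                min(object@trainingLog$val_loss)))
})

setMethod("show", "CNNModel", function(object) {
  cfg <- object@config
  cat(sprintf("CNNModel: filter widths %s x %d filters, %d terms\n",
              paste(cfg$filter_widths, collapse = "/"), cfg$n_filters,
              length(object@labelSpace@termIds)))
})

setMethod("show", "SaliencyProfile", function(object) {
  cat(sprintf("SaliencyProfile: %s / %s, %d residues, peak at residue %d\n",
              object@proteinId, object@termId, length(object@raw),
              which.max(object@profile)))
})
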
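#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("listOrNULL", c("list", "NULL"))

#' Residue-residue contact map
#'
#' A symmetric binary adjacency matrix over the residues of one protein
#' chain, together with the construction metadata (contact definition and
#' distance threshold). Self-contacts are excluded: the diagonal is zero,
#' self-connections are added only inside the graph convolution via the
#' normalized adjacency.
#'
#' @slot adjacency L x L binary matrix, symmetric with zero diagonal.
#' @slot mode Contact definition, one of `"CA_CA"`, `"ANY_ANY"`, `"NBR_NBR"`.
#' @slot threshold Distance threshold in Angstrom (`NA` for `NBR_NBR`, which
#'   uses per-amino-acid radius sums).
#' @export
setClass("ContactMap",
  representation(adjacency = "matrix", mode = "character",
                 threshold = "numeric"))

setValidity("ContactMap", function(object) {
  A <- object@adjacency
  if (nrow(A) != ncol(A)) return("adjacency must be square")
  if (!all(A %in% c(0, 1))) return("adjacency entries must be 0/1")
  if (!isTRUE(all.equal(A, t(A)))) return("adjacency must be symmetric")
  if (any(diag(A) != 0)) return("adjacency diagonal must be zero")
  if (!object@mode %in% c("CA_CA", "ANY_ANY", "NBR_NBR"))
    return("mode must be CA_CA, ANY_ANY or NBR_NBR")
  TRUE
})

setClassUnion("ContactMapOrNULL", c("ContactMap", "NULL"))

#' One protein flowing through the pipeline
#'
#' @slot id Protein identifier.
#' @slot sequence One-letter residue string.
#' @slot coords Optional L x 3 coordinate matrix (one point per residue, in
#'   Angstrom; for synthetic bead chains these are the virtual C-alpha beads).
#' @slot cmap Optional [ContactMap-class].
#' @slot labels Named integer 0/1 vector over the label space (observed,
#'   possibly noisy, annotations). May be empty before label assignment.
#' @slot plantedLabels Named integer 0/1 vector of ground-truth planted
#'   labels (synthetic data only; empty otherwise).
#' @slot motifIndices Named list mapping a term id to the 1-based residue
#'   indices of its planted motif (synthetic data only).
#' @export
setClass("ProteinRecord",
  representation(id = "character", sequence = "character",
                 coords = "matrixOrNULL", cmap = "ContactMapOrNULL",
                 labels = "numeric", plantedLabels = "numeric",
                 motifIndices = "list"),
  prototype(labels = numeric(0), plantedLabels = numeric(0),
            motifIndices = list()))

setValidity("ProteinRecord", function(object) {
  L <- nchar(object@sequence)
  if (!is.null(object@coords) && nrow(object@coords) != L)
    return("coords row count must equal sequence length")
  if (!is.null(object@cmap) && nrow(object@cmap@adjacency) != L)
    return("contact map dimension must equal sequence length")
  TRUE
})

#' Ordered catalogue of selected function terms
#'
#' The trainable label space: term identifiers in deterministic
#' (lexicographic) order with their positive counts, information content,
#' and the class weights w_j = N / N_j+ used by the weighted cross-entropy.
#'
#' @slot termIds Character vector of term identifiers.
#' @slot termNames Character vector of human-readable names.
#' @slot counts Per-term positive example counts N_j+.
#' @slot ic Per-term information content in bits.
#' @slot weights Per-term class weights.
#' @slot nProteins Total number of proteins N behind the counts.
#' @export
setClass("LabelSpace",
  representation(termIds = "character", termNames = "character",
                 counts = "numeric", ic = "numeric", weights = "numeric",
                 nProteins = "numeric"))

setValidity("LabelSpace", function(object) {
  k <- length(object@termIds)
  if (length(object@counts) != k || length(object@ic) != k ||
      length(object@weights) != k || length(object@termNames) != k)
    return("per-term slots must share the length of termIds")
  if (any(object@counts <= 0)) return("every term needs a positive count")
  if (any(object@ic < 0)) return("information content must be >= 0")
  if (anyDuplicated(object@termIds)) return("duplicated term ids")
  TRUE
})

#' Ontology DAG
#'
#' Directed is_a/part_of edges child -> parent over term identifiers, with
#' per-term namespace and obsolete flags. Backed by an igraph graph.
#'
#' @slot graph igraph object with vertex attributes `name` and `namespace`.
#' @slot roots Named character vector mapping namespace to its root term.
#' @export
setClass("OntologyGraph",
  representation(graph = "ANY", roots = "character"))

#' Frozen LSTM language model state
#'
#' Two stacked forward LSTM layers over the 26-symbol residue vocabulary
#' (20 standard + 5 non-standard amino acids + gap), trained as a
#' next-residue predictor and used downstream only as a frozen feature
#' extractor.
#'
#' @slot params Named list of weight arrays.
#' @slot hiddenSize Hidden state width d of each LSTM layer.
#' @slot config Training configuration snapshot.
#' @export
setClass("LanguageModel",
  representation(params = "list", hiddenSize = "numeric", config = "list"))

setClassUnion("LanguageModelOrNULL", c("LanguageModel", "NULL"))

#' Trained GCN function predictor
#'
#' All trainable parameters of the graph convolutional network (fusion
#' mapping, per-layer weights, fully connected head) plus architecture
#' configuration, the label space it predicts over, the frozen language
#' model used for featurization (if any), and the training log.
#'
#' @slot params Named list of weight arrays.
#' @slot config Architecture/training configuration.
#' @slot labelSpace The [LabelSpace-class] the heads predict over.
#' @slot lm Optional frozen [LanguageModel-class].
#' @slot trainingLog Data frame of per-epoch train/validation losses.
#' @export
setClass("GCNModel",
  representation(params = "list", config = "list", labelSpace = "LabelSpace",
                 lm = "LanguageModelOrNULL", trainingLog = "data.frame"))

#' Trained sequence-only CNN baseline
#'
#' DeepGO-style model: parallel one-dimensional convolutions of several
#' filter lengths over the one-hot sequence, ReLU, global max pooling,
#' and a dense sigmoid head with one output per term.
#'
#' @slot params Named list of weight arrays.
#' @slot config Architecture/training configuration.
#' @slot labelSpace The [LabelSpace-class] the head predicts over.
#' @slot trainingLog Data frame of per-epoch train/validation losses.
#' @export
setClass("CNNModel",
  representation(params = "list", config = "list", labelSpace = "LabelSpace",
                 trainingLog = "data.frame"))

#' Per-residue grad-CAM saliency for one (protein, term) pair
#'
#' @slot proteinId Protein identifier.
#' @slot termId Term identifier.
#' @slot raw Non-negative raw class activation map, one value per residue.
#' @slot profile Raw map normalized to max 1 (all-zero maps stay all-zero).
#' @slot layer Tag of the feature-map source layer.
#' @export
setClass("SaliencyProfile",
  representation(proteinId = "character", termId = "character",
                 raw = "numeric", profile = "numeric", layer = "character"))

setValidity("SaliencyProfile", function(object) {
  if (length(object@raw) != length(object@profile))
    return("raw and normalized profiles must share length")
  if (any(object@raw < 0)) return("raw CAM must be non-negative")
  if (any(object@raw > 0) && abs(max(object@profile) - 1) > 1e-9)
    return("normalized profile must peak at 1 when the raw CAM is nonzero")
  TRUE
})
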
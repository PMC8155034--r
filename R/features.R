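#' @include AllClasses.R utils.R
NULL

## Residue vocabulary: 20 standard amino acids (alphabetical), 5 non-standard
## channels (B = Asx, J = Xle, O = Pyl, U = Sec, Z = Glx), and the gap symbol.
## The channel ordering is fixed and recorded in model manifests.
STANDARD_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
NONSTANDARD_AA <- c("B", "J", "O", "U", "Z")
GAP_SYMBOL <- "-"

#' Residue channel vocabulary
#'
#' The fixed 26-channel vocabulary used by the one-hot encoder, the language
#' model, and the CNN baseline: the 20 standard amino acids in alphabetical
#' order, the 5 non-standard channels (B, J, O, U, Z), and the gap symbol.
#'
#' @return Character vector of length 26.
#' @export
#' @examples
#' residueVocabulary()
residueVocabulary <- function() c(STANDARD_AA, NONSTANDARD_AA, GAP_SYMBOL)

#' One-hot encode a residue sequence
#'
#' Each row carries a single 1 in the channel of the residue at that
#' position. Characters outside the 25 amino-acid channels (including
#' ambiguous X) map to the gap channel; a warning reports how many.
#'
#' @param sequence One-letter residue string.
#' @return L x 26 binary matrix with unit row sums.
#' @export
#' @examples
#' X <- oneHotEncode("ACDX")
#' rowSums(X)  # all 1
oneHotEncode <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nchar(sequence) >= 1L)
  vocab <- residueVocabulary()
  chars <- strsplit(toupper(sequence), "")[[1]]
  idx <- match(chars, vocab)
  nUnknown <- sum(is.na(idx))
  if (nUnknown > 0) {
    warning(sprintf("%d residue character(s) outside the vocabulary mapped to the gap channel",
                    nUnknown))
    idx[is.na(idx)] <- length(vocab)
  }
  X <- matrix(0, length(chars), length(vocab),
              dimnames = list(NULL, vocab))
  X[cbind(seq_along(chars), idx)] <- 1
  X
}

#' Initialise the learnable feature-fusion parameters
#'
#' The fusion mapping combines the frozen language-model hidden states with
#' the one-hot encoding into the input channels of the first graph layer:
#' `H_input = ReLU(H_LM W_LM + X W_X + b)`. `W_LM` is dropped when the LM
#' pathway is disabled (one-hot-only baseline).
#'
#' @param lmDim Hidden width d of the language model (0 disables the LM path).
#' @param outDim Input channel width c0 of the first graph layer.
#' @param vocabSize Number of one-hot channels (26).
#' @return Named list of parameter arrays `W_LM` (optional), `W_X`, `b`.
#' @export
initFusionParams <- function(lmDim, outDim, vocabSize = 26L) {
  p <- list()
  if (lmDim > 0) p$W_LM <- glorot(lmDim, outDim)
  p$W_X <- glorot(vocabSize, outDim)
  p$b <- numeric(outDim)
  p
}

#' Fuse language-model features with the one-hot encoding
#'
#' Computes `ReLU(H_LM W_LM + X W_X + b)` row-wise over residues. When
#' `HLM` is `NULL` (LM pathway disabled) the first term is omitted.
#'
#' @param HLM L x d language-model feature matrix, or `NULL`.
#' @param X L x 26 one-hot matrix.
#' @param params Fusion parameters from [initFusionParams()].
#' @return L x c0 non-negative feature matrix.
#' @export
fuseFeatures <- function(HLM, X, params) {
  if (ncol(X) != nrow(params$W_X))
    stop(sprintf("X has %d columns but W_X expects %d",
                 ncol(X), nrow(params$W_X)))
  if (!is.null(HLM)) {
    if (nrow(HLM) != nrow(X))
      stop("H_LM and X must have the same number of residue rows")
    if (is.null(params$W_LM))
      stop("fusion parameters lack W_LM but an LM feature matrix was given")
    if (ncol(HLM) != nrow(params$W_LM))
      stop(sprintf("H_LM has %d columns but W_LM expects %d",
                   ncol(HLM), nrow(params$W_LM)))
    Z <- HLM %*% params$W_LM + X %*% params$W_X
  } else {
    Z <- X %*% params$W_X
  }
  relu(sweep(Z, 2L, params$b, "+"))
}
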
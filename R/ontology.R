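#' @include AllClasses.R utils.R
NULL

## Evidence codes treated as experimental-or-curated: EXP plus direct assay,
## physical interaction, mutant phenotype, genetic interaction, expression
## pattern, traceable author statement and inferred-by-curator.
EXP_CODES <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP", "TAS", "IC")
KNOWN_CODES <- c(EXP_CODES, "IEA")

#' Parse a minimal OBO 1.2 ontology file
#'
#' Reads `[Term]` stanzas (id, name, namespace, is_a, `relationship:
#' part_of`, is_obsolete) into an [OntologyGraph-class]. Edges run child to
#' parent; `part_of` edges are treated like `is_a` when `usePartOf` is set
#' (the default). Obsolete terms are dropped. The graph is checked to be
#' acyclic; each namespace's root is the term without outgoing edges.
#'
#' @param path Path to an OBO file.
#' @param usePartOf Treat `part_of` like `is_a` for propagation.
#' @return An [OntologyGraph-class].
#' @export
readOBO <- function(path, usePartOf = TRUE) {
  lines <- readLines(path)
  stanzaStarts <- grep("^\\[", lines)
  termIds <- character(0); termNames <- character(0)
  termNs <- character(0); obsolete <- logical(0)
  edges <- list()
  for (s in seq_along(stanzaStarts)) {
    from <- stanzaStarts[s]
    if (lines[from] != "[Term]") next
    to <- if (s < length(stanzaStarts)) stanzaStarts[s + 1] - 1 else length(lines)
    block <- lines[from:to]
    getv <- function(tag) sub(paste0("^", tag, ":\\s*"), "",
                              grep(paste0("^", tag, ":"), block, value = TRUE))
    id <- getv("id")[1]
    if (is.na(id)) next
    name <- getv("name")
    ns <- getv("namespace")
    obs <- any(grepl("^is_obsolete:\\s*true", block))
    parents <- sub("\\s*!.*$", "", getv("is_a"))
    if (usePartOf) {
      po <- grep("^relationship:\\s*part_of\\s", block, value = TRUE)
      parents <- c(parents,
                   sub("\\s*!.*$", "",
                       sub("^relationship:\\s*part_of\\s+", "", po)))
    }
    termIds <- c(termIds, id)
    termNames <- c(termNames, if (length(name)) name[1] else id)
    termNs <- c(termNs, if (length(ns)) ns[1] else "unknown")
    obsolete <- c(obsolete, obs)
    if (length(parents)) edges[[id]] <- trimws(parents)
  }
  keep <- !obsolete
  termIds <- termIds[keep]; termNames <- termNames[keep]; termNs <- termNs[keep]
  el <- do.call(rbind, lapply(termIds, function(id) {
    p <- intersect(edges[[id]], termIds)
    if (length(p)) cbind(id, p) else NULL
  }))
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(termIds, term_name = termNames, namespace = termNs)
  if (!is.null(el)) g <- g + igraph::edges(t(el))
  if (!igraph::is_dag(g)) stop("ontology graph is cyclic")
  roots <- vapply(split(termIds, termNs), function(ids) {
    deg <- igraph::degree(g, v = ids, mode = "out")
    r <- ids[deg == 0]
    if (length(r) != 1L)
      stop("namespace without a unique root term")
    r
  }, character(1))
  new("OntologyGraph", graph = g, roots = roots)
}

#' Ancestors of a term (excluding itself)
#'
#' @param ontology An [OntologyGraph-class].
#' @param term Term identifier.
#' @return Character vector of ancestor term ids (unordered).
#' @export
termAncestors <- function(ontology, term) {
  g <- ontology@graph
  if (!term %in% igraph::V(g)$name)
    stop(sprintf("term %s absent from the ontology graph", term))
  anc <- igraph::subcomponent(g, term, mode = "out")$name
  setdiff(anc, term)
}

#' Filter an annotation table by evidence policy
#'
#' `EXP_only` retains exactly the experimental/curated codes EXP, IDA, IPI,
#' IMP, IGI, IEP, TAS, IC; `EXP_and_IEA` additionally retains IEA
#' (electronically inferred). Rows with unknown codes are dropped with a
#' warning that counts them. Duplicate (protein, term) rows are collapsed.
#'
#' @param table Data frame with columns `protein_id`, `term_id`, `evidence`.
#' @param policy `"EXP_only"` or `"EXP_and_IEA"`.
#' @return Filtered data frame.
#' @export
filterByEvidence <- function(table, policy = c("EXP_only", "EXP_and_IEA")) {
  policy <- match.arg(policy)
  if (!nrow(table)) return(table)
  unknown <- !table$evidence %in% KNOWN_CODES
  if (any(unknown))
    warning(sprintf("dropped %d row(s) with unknown evidence code(s): %s",
                    sum(unknown),
                    paste(unique(table$evidence[unknown]), collapse = ", ")))
  allowed <- if (policy == "EXP_only") EXP_CODES else c(EXP_CODES, "IEA")
  out <- table[table$evidence %in% allowed, , drop = FALSE]
  out[!duplicated(out[, c("protein_id", "term_id")]), , drop = FALSE]
}

#' Propagate annotations up the ontology DAG
#'
#' Closes each (protein, term) pair under ancestry: every ancestor up to,
#' but excluding, the namespace root is added. Idempotent; output is a
#' superset of the input.
#'
#' @param table Data frame with columns `protein_id`, `term_id` (an
#'   `evidence` column, if present, is carried over from the source row).
#' @param ontology An [OntologyGraph-class].
#' @return Propagated, deduplicated data frame sorted by protein then term.
#' @export
propagateAnnotations <- function(table, ontology) {
  if (!nrow(table)) return(table)
  terms <- unique(table$term_id)
  missing <- setdiff(terms, igraph::V(ontology@graph)$name)
  if (length(missing))
    stop(sprintf("annotated term(s) absent from the ontology: %s",
                 paste(missing, collapse = ", ")))
  anc <- lapply(terms, function(t)
    c(t, setdiff(termAncestors(ontology, t), ontology@roots)))
  names(anc) <- terms
  pieces <- lapply(seq_len(nrow(table)), function(i) {
    tt <- anc[[table$term_id[i]]]
    out <- data.frame(protein_id = table$protein_id[i], term_id = tt,
                      stringsAsFactors = FALSE)
    if ("evidence" %in% names(table)) out$evidence <- table$evidence[i]
    out
  })
  out <- do.call(rbind, pieces)
  out <- out[!duplicated(out[, c("protein_id", "term_id")]), , drop = FALSE]
  out <- out[order(out$protein_id, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Information content of an annotation frequency
#'
#' `IC = -log2(prob)` in bits, where `prob` is the probability of observing
#' the term in the annotation corpus. Rare (specific) terms have high IC.
#'
#' @param prob Probability in `(0, 1]`.
#' @return IC in bits.
#' @export
#' @examples
#' informationContent(0.5)    # 1 bit
#' informationContent(2^-10)  # 10 bits: a very specific term
informationContent <- function(prob) {
  if (any(prob <= 0) || any(prob > 1))
    stop("prob must be in (0, 1]")
  -log2(prob)
}

ecDepth <- function(id) lengths(strsplit(id, ".", fixed = TRUE))

#' Select trainable terms and build the label space
#'
#' Retains terms whose positive count satisfies
#' `min_count <= N_j+ <= max_count` (defaults 50 and 5000). For EC-style
#' spaces (`ecMode = TRUE`) only identifiers of depth 3 or 4 (`a.b.c`,
#' `a.b.c.d`) are eligible. Class weights are `w_j = N / N_j+` with N the
#' total number of distinct proteins in `table` (or `nProteins` if given);
#' IC is computed from the same corpus unless `icProb` supplies external
#' frequencies. Terms are ordered lexicographically for determinism.
#'
#' @param table Annotation data frame (`protein_id`, `term_id`), already
#'   evidence-filtered and, for GO, propagated.
#' @param min_count,max_count Inclusive positive-count bounds.
#' @param ecMode Restrict to EC identifiers of depth 3-4.
#' @param nProteins Override for the total protein count N.
#' @param icProb Optional named probability vector for IC (external corpus).
#' @param termNames Optional named vector of term names.
#' @return A [LabelSpace-class].
#' @export
selectTerms <- function(table, min_count = 50L, max_count = 5000L,
                        ecMode = FALSE, nProteins = NULL, icProb = NULL,
                        termNames = NULL) {
  stopifnot(min_count <= max_count)
  tab <- table[!duplicated(table[, c("protein_id", "term_id")]), ,
               drop = FALSE]
  N <- if (is.null(nProteins)) length(unique(tab$protein_id)) else nProteins
  counts <- table(tab$term_id)
  ids <- names(counts)
  if (ecMode) ids <- ids[ecDepth(ids) %in% c(3L, 4L)]
  ids <- ids[counts[ids] >= min_count & counts[ids] <= max_count]
  if (!length(ids))
    stop("no term satisfies the count bounds; lower min_count or raise max_count")
  ids <- sort(ids)
  nPos <- as.numeric(counts[ids])
  prob <- if (is.null(icProb)) nPos / N else as.numeric(icProb[ids])
  nms <- if (is.null(termNames)) ids else {
    out <- termNames[ids]; out[is.na(out)] <- ids[is.na(out)]; unname(out)
  }
  new("LabelSpace", termIds = ids, termNames = nms, counts = nPos,
      ic = informationContent(prob), weights = N / nPos, nProteins = N)
}

#' Encode protein annotations as a paired-indicator label array
#'
#' Builds the N x |terms| x 2 binary array consumed by the two-way softmax
#' heads: `y[i, j, 1] = 1, y[i, j, 2] = 0` when protein i carries term j,
#' and `(0, 1)` otherwise; exactly one indicator of each pair is 1.
#'
#' @param records List of [ProteinRecord-class] objects with `labels` set,
#'   or a data frame (`protein_id`, `term_id`) plus `proteinIds`.
#' @param space A [LabelSpace-class].
#' @param proteinIds Protein ordering when `records` is a data frame.
#' @return 3-d array with dimnames on proteins and terms.
#' @export
encodeLabels <- function(records, space, proteinIds = NULL) {
  ids <- space@termIds
  if (is.data.frame(records)) {
    stopifnot(!is.null(proteinIds))
    pos <- matrix(0, length(proteinIds), length(ids),
                  dimnames = list(proteinIds, ids))
    hit <- records[records$term_id %in% ids &
                     records$protein_id %in% proteinIds, , drop = FALSE]
    pos[cbind(hit$protein_id, hit$term_id)] <- 1
  } else {
    proteinIds <- vapply(records, function(r) r@id, character(1))
    pos <- do.call(rbind, lapply(records, function(r) {
      v <- r@labels[ids]
      v[is.na(v)] <- 0
      as.numeric(v)
    }))
    dimnames(pos) <- list(proteinIds, ids)
  }
  y <- array(0, dim = c(nrow(pos), length(ids), 2L),
             dimnames = list(proteinIds, ids, c("pos", "neg")))
  y[, , 1] <- pos
  y[, , 2] <- 1 - pos
  y
}
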
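#' @include utils.R
NULL

#' Protein-centric maximum F-score (Fmax)
#'
#' CAFA-style Fmax: at each decision threshold t on the grid, a protein's
#' predicted term set is the terms scoring at least t. Precision is averaged
#' over proteins with at least one predicted term; recall is averaged over
#' proteins with at least one true term. `F(t)` is the harmonic mean (0 when
#' both are 0) and Fmax the maximum over the grid. The default grid is
#' 0.01, 0.02, ..., 1.00: t = 0, at which every term is trivially predicted
#' for every protein, is excluded.
#'
#' @param scores N x T score matrix in `[0, 1]`.
#' @param labels N x T binary label matrix.
#' @param thresholds Threshold grid.
#' @return List with `fmax`, the achieving `threshold`, and the per-threshold
#'   `curve` (threshold, precision, recall, f) data frame.
#' @export
#' @examples
#' s <- rbind(c(0.9, 0.4), c(0.4, 0.3))
#' y <- rbind(c(1, 0), c(0, 1))
#' fmax(s, y)$fmax
fmax <- function(scores, labels, thresholds = seq(0.01, 1, by = 0.01)) {
  stopifnot(all(dim(scores) == dim(labels)))
  posPerProt <- rowSums(labels)
  if (!any(posPerProt > 0))
    stop("fmax needs at least one protein with at least one positive label")
  hasPos <- posPerProt > 0
  curve <- data.frame(threshold = thresholds, precision = NA_real_,
                      recall = NA_real_, f = NA_real_)
  for (k in seq_along(thresholds)) {
    t <- thresholds[k]
    pred <- scores >= t
    npred <- rowSums(pred)
    tp <- rowSums(pred & labels == 1)
    covered <- npred > 0
    pr <- if (any(covered)) mean(tp[covered] / npred[covered]) else 0
    rc <- mean(tp[hasPos] / posPerProt[hasPos])
    f <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    curve$precision[k] <- pr; curve$recall[k] <- rc; curve$f[k] <- f
  }
  best <- which.max(curve$f)
  list(fmax = curve$f[best], threshold = curve$threshold[best], curve = curve)
}

#' Term-centric area under the precision-recall curve
#'
#' Non-interpolated step-wise area (average-precision style): proteins are
#' ranked by score, tied scores form a single step, and the area is the sum
#' of precision times the recall increment at each distinct threshold.
#'
#' @param scores Score vector over proteins for one term.
#' @param labels Binary label vector.
#' @return AUPR in `[0, 1]`.
#' @export
termAupr <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  nPos <- sum(labels == 1)
  nNeg <- sum(labels == 0)
  if (nPos == 0 || nNeg == 0)
    stop("term AUPR needs at least one positive and one negative")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))          # tie groups, descending score
  tpByGrp <- tapply(y, grp, sum)
  nByGrp <- tapply(rep(1, length(y)), grp, sum)
  tp <- cumsum(tpByGrp)
  n <- cumsum(nByGrp)
  precision <- tp / n
  recall <- tp / nPos
  dRecall <- diff(c(0, recall))
  sum(precision * dRecall)
}

#' Macro-averaged term-centric AUPR
#'
#' Averages [termAupr()] over columns; terms without both a positive and a
#' negative example are skipped and reported in a message.
#'
#' @param scores N x T score matrix.
#' @param labels N x T binary label matrix.
#' @return List with `macro` (mean AUPR), `per_term` (named vector), and
#'   `skipped` (term indices/names lacking both classes).
#' @export
macroAupr <- function(scores, labels) {
  stopifnot(all(dim(scores) == dim(labels)))
  nms <- colnames(labels)
  if (is.null(nms)) nms <- as.character(seq_len(ncol(labels)))
  ok <- vapply(seq_len(ncol(labels)), function(j)
    any(labels[, j] == 1) && any(labels[, j] == 0), logical(1))
  if (any(!ok))
    message(sprintf("macroAupr: skipped %d term(s) lacking both classes",
                    sum(!ok)))
  per <- vapply(which(ok), function(j) termAupr(scores[, j], labels[, j]),
                numeric(1))
  names(per) <- nms[ok]
  list(macro = mean(per), per_term = per, skipped = nms[!ok])
}

#' Bootstrap summary of an evaluation metric
#'
#' Resamples proteins (rows) with replacement `n_boot` times, recomputes the
#' metric on each replicate, and summarises the replicate distribution.
#' Replicates on which the metric is undefined (e.g. a resample without
#' positives) are skipped.
#'
#' @param metric Function of `(scores, labels)` returning a scalar.
#' @param scores N x T score matrix.
#' @param labels N x T binary label matrix.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return List with `mean`, `sd`, `median`, `q25`, `q75`, `values`.
#' @export
bootstrapMetric <- function(metric, scores, labels, n_boot = 100L, seed = 1L) {
  stopifnot(n_boot >= 1L)
  n <- nrow(scores)
  vals <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(metric(scores[idx, , drop = FALSE],
                      labels[idx, , drop = FALSE]),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  vals <- vals[!is.na(vals)]
  list(mean = mean(vals), sd = if (length(vals) > 1) sd(vals) else 0,
       median = median(vals),
       q25 = unname(quantile(vals, 0.25)),
       q75 = unname(quantile(vals, 0.75)),
       values = vals)
}

#' Residue-level AUROC of a saliency profile against known sites
#'
#' Builds the ROC curve by sliding a threshold over the saliency values
#' (tied values form one step) and integrates by the trapezoid rule, which
#' equals the rank-averaged Mann-Whitney statistic.
#'
#' @param saliency Numeric saliency vector (a [SaliencyProfile-class] is
#'   also accepted).
#' @param sites Binary site vector of the same length, at least one positive
#'   and one negative.
#' @return AUROC in `[0, 1]`.
#' @export
#' @examples
#' residueAuroc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))  # 1
residueAuroc <- function(saliency, sites) {
  if (is(saliency, "SaliencyProfile")) saliency <- saliency@profile
  stopifnot(length(saliency) == length(sites))
  nPos <- sum(sites == 1); nNeg <- sum(sites == 0)
  if (nPos == 0 || nNeg == 0)
    stop("site profile must contain at least one positive and one negative")
  thr <- sort(unique(saliency), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(saliency >= t & sites == 1) / nPos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(saliency >= t & sites == 0) / nNeg,
                numeric(1))
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  if (tail(fpr, 1) < 1 || tail(tpr, 1) < 1) { tpr <- c(tpr, 1); fpr <- c(fpr, 1) }
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}
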
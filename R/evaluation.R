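.truthMap <- function(truth) {
  stopifnot(all(c("source", "target") %in% names(truth)))
  if (!nrow(truth)) stop("empty true mapping")
  if (anyDuplicated(truth$source) || anyDuplicated(truth$target))
    stop("true mapping must be one-to-one")
  stats::setNames(truth$target, truth$source)
}

#' Node correctness of an alignment
#'
#' The ratio of aligned node pairs that agree with the known true mapping
#' to the size of that mapping.
#'
#' @param a an [Alignment-class]
#' @param truth data.frame with columns \code{source}, \code{target}
#'   (injective)
#' @return numeric in \[0, 1\]
#' @export
nodeCorrectness <- function(a, truth) {
  stopifnot(is(a, "Alignment"))
  tm <- .truthMap(truth)
  p <- a@pairs
  sum(!is.na(tm[p$source]) & tm[p$source] == p$target) / length(tm)
}

#' Alignment score: unity-based normalization of node correctness
#'
#' Min-max feature scaling of a set of NC values taken over one benchmark
#' run, so the best alignment of the run scores 1 and the worst 0. When all
#' values are equal the scaling is degenerate and the raw NC values are
#' returned unchanged.
#'
#' @param ncValues numeric vector of node-correctness values
#' @return numeric vector of the same length, in \[0, 1\]
#' @export
alignmentScore <- function(ncValues) {
  stopifnot(length(ncValues) >= 1)
  lo <- min(ncValues); hi <- max(ncValues)
  if (hi == lo) return(ncValues)
  (ncValues - lo) / (hi - lo)
}

#' Confusion counts of an alignment against the true mapping
#'
#' At the natural operating point every source node is mapped, so there are
#' no predicted negatives: \code{tp} counts correctly mapped pairs,
#' \code{fp} mapped pairs contradicting the truth, \code{fn} truth pairs
#' missing from the alignment, and \code{tn} is 0 by construction (true
#' negatives only arise in the thresholded ROC setting).
#'
#' @inheritParams nodeCorrectness
#' @return named integer vector \code{c(tp, fp, tn, fn)}
#' @export
confusionCounts <- function(a, truth) {
  stopifnot(is(a, "Alignment"))
  tm <- .truthMap(truth)
  p <- a@pairs
  known <- !is.na(tm[p$source])
  tp <- sum(known & tm[p$source] == p$target)
  fp <- sum(known & tm[p$source] != p$target)
  fn <- length(tm) - tp
  c(tp = as.integer(tp), fp = as.integer(fp), tn = 0L, fn = as.integer(fn))
}

# Threshold sweep over scored binary instances; returns curve + trapezoid
# AUC. Anchored at (0,0) and (1,1).
.rocSweep <- function(scores, labels) {
  pos <- sum(labels); neg <- sum(!labels)
  if (pos == 0 || neg == 0)
    return(list(curve = data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                auc = NA_real_))
  o <- order(-scores)
  scores <- scores[o]; labels <- labels[o]
  tp <- cumsum(labels); fp <- cumsum(!labels)
  last <- !duplicated(scores, fromLast = TRUE)   # one point per threshold
  tpr <- c(0, tp[last] / pos, 1)
  fpr <- c(0, fp[last] / neg, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' ROC curve and AUC from per-pair alignment scores
#'
#' Each aligned pair is an instance labelled correct/incorrect against the
#' true mapping, scored by its similarity. A threshold swept in descending
#' score order classifies pairs scoring at least the threshold as predicted
#' matches; TPR and FPR at each threshold give the curve (anchored at (0,0)
#' and (1,1)), and AUC is computed by the trapezoid rule. With all scores
#' equal the curve degenerates to the two anchors and AUC is 0.5. When the
#' alignment contains only correct (or only incorrect) pairs the curve is
#' undefined and AUC is \code{NA}.
#'
#' @inheritParams nodeCorrectness
#' @return list with \code{curve} (data.frame \code{fpr}, \code{tpr}) and
#'   \code{auc}
#' @export
rocAuc <- function(a, truth) {
  stopifnot(is(a, "Alignment"))
  tm <- .truthMap(truth)
  p <- a@pairs
  labels <- !is.na(tm[p$source]) & tm[p$source] == p$target
  if (length(unique(p$score)) == 1L)
    return(list(curve = data.frame(fpr = c(0, 1), tpr = c(0, 1)), auc = 0.5))
  .rocSweep(p$score, labels)
}

.f1 <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]; fn <- counts[["fn"]]
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

#' F1 aggregates over a benchmark of alignments
#'
#' Per-alignment F1 is the harmonic mean of precision and recall (0 when
#' both vanish). The aggregates are the mean, the maximum, and a
#' noise-level-normalized mean: F1 values are min-max scaled within each
#' noise level, then averaged (degenerate all-equal groups keep their raw
#' values).
#'
#' @param countsList list of confusion-count vectors (see
#'   [confusionCounts()])
#' @param noiseLabels vector, one noise level per alignment
#' @return named list \code{f1_avg}, \code{f1_max}, \code{f1_norm}, plus
#'   the per-alignment values as \code{f1}
#' @export
f1Scores <- function(countsList, noiseLabels) {
  stopifnot(length(countsList) >= 1,
            length(noiseLabels) == length(countsList))
  f1 <- vapply(countsList, .f1, numeric(1))
  normed <- unlist(lapply(split(f1, noiseLabels), alignmentScore),
                   use.names = FALSE)
  list(f1_avg = mean(f1), f1_max = max(f1), f1_norm = mean(normed), f1 = f1)
}

#' Matthews correlation coefficient
#'
#' \code{(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))}, the
#' chi-square-equivalent correlation of a 2x2 contingency table: +1 for a
#' perfect alignment, 0 for no valid information, -1 for complete
#' inconsistency. A zero denominator yields 0 by convention.
#'
#' @param counts named vector with \code{tp}, \code{fp}, \code{tn},
#'   \code{fn}
#' @return numeric in \[-1, 1\]
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts[["tp"]]); fp <- as.numeric(counts[["fp"]])
  tn <- as.numeric(counts[["tn"]]); fn <- as.numeric(counts[["fn"]])
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Evaluate one alignment against the true mapping
#'
#' @inheritParams nodeCorrectness
#' @return an [EvaluationReport-class]
#' @export
evaluateAlignment <- function(a, truth) {
  counts <- confusionCounts(a, truth)
  tp <- counts[["tp"]]; fp <- counts[["fp"]]; fn <- counts[["fn"]]
  roc <- rocAuc(a, truth)
  new("EvaluationReport",
      nc = nodeCorrectness(a, truth),
      counts = counts,
      tpr = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
      fpr = if (fp + counts[["tn"]] == 0) 0 else
        fp / (fp + counts[["tn"]]),
      auc = roc$auc,
      f1 = .f1(counts),
      mcc = mcc(counts))
}

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport\n")
  cat(sprintf("  NC: %.4f | F1: %.4f | AUC: %s | MCC: %.4f\n",
              object@nc, object@f1,
              ifelse(is.na(object@auc), "NA", sprintf("%.4f", object@auc)),
              object@mcc))
  cat(sprintf("  tp=%d fp=%d tn=%d fn=%d | TPR=%.4f FPR=%.4f\n",
              object@counts[["tp"]], object@counts[["fp"]],
              object@counts[["tn"]], object@counts[["fn"]],
              object@tpr, object@fpr))
})

#' Percentage improvement of one score over another
#'
#' \code{100 * (a - b) / b}: the standard relative-improvement figure used
#' when comparing overall mean alignment scores between methods.
#'
#' @param a,b numeric scalars, \code{b != 0}
#' @return percentage (e.g. 25.88 for a 25.88\% improvement)
#' @export
percentImprovement <- function(a, b) {
  stopifnot(b != 0)
  100 * (a - b) / b
}
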
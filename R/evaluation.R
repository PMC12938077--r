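#' @include AllClasses.R
NULL

.canonicalPairKey <- function(config) {
  sp <- config@stackedPairs
  if (!nrow(sp)) return("")
  sp <- t(apply(sp, 1, sort))
  sp <- sp[order(sp[, 1], sp[, 2]), , drop = FALSE]
  paste(sp[, 1], sp[, 2], sep = "-", collapse = ";")
}

#' Exact-match configuration accuracy
#'
#' Fraction of junctions whose predicted stacking configuration equals the
#' ground truth as a set of stacked pairs — one spurious or missing stack
#' makes the whole junction wrong. This is the headline metric for
#' junctions of order below five; a warning is emitted when higher-order
#' junctions are included (use [pairwiseAccuracy()] there).
#'
#' @param predictions,truths aligned lists of
#'   [StackingConfiguration-class] objects (matched by position; ids and
#'   orders must agree).
#' @return Accuracy in `[0, 1]`.
#' @export
configurationAccuracy <- function(predictions, truths) {
  stopifnot(length(predictions) == length(truths), length(truths) > 0)
  ok <- vapply(seq_along(truths), function(i) {
    p <- predictions[[i]]; t <- truths[[i]]
    if (p@junctionId != t@junctionId || p@order != t@order)
      stop("prediction/truth mismatch at position ", i, " (",
           p@junctionId, " vs ", t@junctionId, ")")
    .canonicalPairKey(p) == .canonicalPairKey(t)
  }, logical(1))
  orders <- vapply(truths, function(t) t@order, integer(1))
  if (any(orders >= 5L))
    warning("exact-match accuracy on junctions of order >= 5; ",
            "pairwise accuracy is the recommended metric there")
  mean(ok)
}

#' Pairwise accuracy of a junction prediction
#'
#' The fraction of cyclically adjacent stem pairs whose stacked/unstacked
#' status is predicted correctly: PA = (1/n) * sum over the n adjacent
#' pairs of the agreement indicator. The tractable per-junction metric for
#' junctions of order five and above; invariant under cyclic relabeling of
#' the stems.
#'
#' @param prediction,truth [StackingConfiguration-class] objects for the
#'   same junction (equal order required).
#' @return PA in `[0, 1]`.
#' @export
pairwiseAccuracy <- function(prediction, truth) {
  stopifnot(is(prediction, "StackingConfiguration"),
            is(truth, "StackingConfiguration"))
  if (prediction@order != truth@order)
    stop("order mismatch between prediction and truth")
  n <- truth@order
  em <- .cycleEdges(n)
  status <- function(config) {
    key <- paste(config@stackedPairs[, 1], config@stackedPairs[, 2])
    paste(em[, 1], em[, 2]) %in% key |
      paste(em[, 2], em[, 1]) %in% key
  }
  mean(status(prediction) == status(truth))
}

#' Mean pairwise accuracy over a junction set
#'
#' Macro-average (per junction, then averaged) by default, matching the
#' convention of reporting the average PA across structures; `pooled`
#' instead pools all adjacent pairs before averaging.
#'
#' @param predictions,truths aligned configuration lists.
#' @param method `"macro"` (default) or `"pooled"`.
#' @return Mean PA in `[0, 1]`.
#' @export
meanPairwiseAccuracy <- function(predictions, truths,
                                 method = c("macro", "pooled")) {
  method <- match.arg(method)
  stopifnot(length(predictions) == length(truths), length(truths) > 0)
  pa <- vapply(seq_along(truths), function(i)
    pairwiseAccuracy(predictions[[i]], truths[[i]]), numeric(1))
  if (method == "macro") return(mean(pa))
  n <- vapply(truths, function(t) if (t@order == 2L) 1L else t@order,
              integer(1))
  sum(pa * n) / sum(n)
}

#' Binary classification metrics for pairwise stacking
#'
#' Computes the standard confusion-matrix metrics at a probability
#' threshold — accuracy, precision, recall, F1 and Cohen's Kappa — plus
#' the threshold-free AUC (rank statistic over the predicted
#' probabilities, via ROC analysis). With a single class present the AUC
#' is undefined and returned as `NA` with a warning, not 0.5.
#'
#' @param labels 0/1 ground-truth vector.
#' @param probabilities predicted probabilities, same length.
#' @param threshold decision cutoff (label 1 when strictly above).
#' @return list: `confusion` (2x2 table, truth in rows), `accuracy`,
#'   `precision`, `recall`, `f1`, `kappa`, `auc`.
#' @export
binaryMetrics <- function(labels, probabilities, threshold = 0.5) {
  stopifnot(length(labels) == length(probabilities), length(labels) > 0)
  labels <- as.integer(labels)
  pred <- as.integer(probabilities > threshold)
  confusion <- table(truth = factor(labels, levels = c(0, 1)),
                     predicted = factor(pred, levels = c(0, 1)))
  tp <- confusion["1", "1"]; tn <- confusion["0", "0"]
  fp <- confusion["0", "1"]; fn <- confusion["1", "0"]
  n <- sum(confusion)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (isTRUE(precision + recall > 0)) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_
  auc <- if (length(unique(labels)) < 2L) {
    warning("AUC undefined with a single class present")
    NA_real_
  } else {
    as.numeric(pROC::auc(pROC::roc(labels, probabilities, quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }
  list(confusion = confusion, accuracy = po, precision = precision,
       recall = recall, f1 = f1, kappa = kappa, auc = auc)
}

#' Configuration-level confusion matrix
#'
#' Cross-tabulates predicted against true configuration labels (H_i-H_j
#' notation) over a junction set, highlighting which stacking patterns are
#' confused with which.
#'
#' @param predictions,truths aligned configuration lists.
#' @return A table (truth in rows, prediction in columns).
#' @export
configurationConfusion <- function(predictions, truths) {
  stopifnot(length(predictions) == length(truths))
  p <- vapply(predictions, configurationLabel, character(1))
  t <- vapply(truths, configurationLabel, character(1))
  lev <- sort(unique(c(p, t)))
  table(truth = factor(t, levels = lev), predicted = factor(p, levels = lev))
}
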
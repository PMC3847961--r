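# Scoring inferred networks against a reference.

#' Upper-triangle pair scores of a symmetric matrix
#'
#' Flattens a symmetric score matrix into the per-pair vector used for ROC
#' evaluation, named `"a|b"` with the smaller gene ID first, in the same
#' pair order as [topology_pairs()].
#'
#' @param z symmetric numeric matrix with gene dimnames.
#' @return named numeric vector of length `choose(n, 2)`.
#' @export
pair_scores <- function(z) {
  if (!is.matrix(z) || nrow(z) != ncol(z)) {
    stop("'z' must be a square matrix", call. = FALSE)
  }
  ids <- rownames(z) %||% as.character(seq_len(nrow(z)))
  idx <- which(upper.tri(z), arr.ind = TRUE)
  a <- ids[idx[, 1L]]
  b <- ids[idx[, 2L]]
  stats::setNames(z[idx], paste(pmin(a, b), pmax(a, b), sep = "|"))
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' positive pair outranks a randomly chosen negative pair, with ties
#' counted 1/2. Identical to the trapezoidal area under the
#' threshold-sweep ROC curve ([roc_curve()]), and invariant under strictly
#' increasing transforms of the scores.
#'
#' @param scores numeric vector of per-pair scores.
#' @param labels logical (or 0/1) vector: `TRUE` for reference (positive)
#'   pairs. Needs at least one positive and one negative.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.4, 0.7, 0.1), c(TRUE, TRUE, FALSE, FALSE))  # 0.75
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(labels) ||
      !all(is.finite(scores))) {
    stop("'scores' and 'labels' must be finite vectors of equal length",
         call. = FALSE)
  }
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("need at least one positive and one negative pair", call. = FALSE)
  }
  r <- rank(scores)  # average ranks handle ties as 1/2 wins
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold-sweep ROC curve
#'
#' Sweeps the decision threshold over every distinct score and reports the
#' (false positive rate, true positive rate) staircase, from (0, 0) to
#' (1, 1). The trapezoidal area under this curve equals [roc_auc()].
#'
#' @inheritParams roc_auc
#' @return data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("need at least one positive and one negative pair", call. = FALSE)
  }
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(scores >= t & labels) / n1, numeric(1L))
  fpr <- vapply(th, function(t) sum(scores >= t & !labels) / n0, numeric(1L))
  data.frame(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Confusion counts
#'
#' Container for true/false positive/negative counts. Counts are
#' real-valued because the reporting convention rescales them (see
#' [rescale_confusion()]).
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @return object of class `confusion_counts` (named numeric vector).
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("confusion counts must be finite and >= 0", call. = FALSE)
  }
  structure(v, class = "confusion_counts")
}

#' Rescale confusion counts to per-hundred pairs
#'
#' The report convention: `(tp, fp)` are scaled so they sum to 100, and
#' `(tn, fn)` likewise, before sensitivity/specificity/accuracy are
#' computed. Idempotent, and it leaves sensitivity, specificity and
#' accuracy (as defined in [confusion_metrics()]) unchanged.
#'
#' @param counts a `confusion_counts` object (or named vector with
#'   `tp`, `fp`, `tn`, `fn`).
#' @return rescaled `confusion_counts`.
#' @export
#' @examples
#' rescale_confusion(confusion_counts(5, 15, 30, 10))
rescale_confusion <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  if (tp + fp == 0 || tn + fn == 0) {
    stop("cannot rescale: tp+fp and tn+fn must both be positive",
         call. = FALSE)
  }
  confusion_counts(tp * 100 / (tp + fp), fp * 100 / (tp + fp),
                   tn * 100 / (tn + fn), fn * 100 / (tn + fn))
}

#' Sensitivity, specificity and prediction accuracy
#'
#' Percentages from confusion counts:
#' sensitivity `= TP / (TP + FN) * 100`,
#' specificity `= TN / (TN + FP) * 100`, and
#' prediction accuracy `= (TP + TN) / (TP + FP + TN + FN) * 100`.
#' Values are returned unrounded; report display rounds to one decimal,
#' half up ([round_half_up()]).
#'
#' @inheritParams rescale_confusion
#' @return named numeric vector `sensitivity`, `specificity`, `accuracy`
#'   (percentages, unrounded).
#' @export
#' @examples
#' m <- confusion_metrics(confusion_counts(2.42, 97.58, 99.95, 0.05))
#' round_half_up(m, 1)
confusion_metrics <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  if (tp + fn == 0) stop("sensitivity undefined: tp + fn = 0", call. = FALSE)
  if (tn + fp == 0) stop("specificity undefined: tn + fp = 0", call. = FALSE)
  c(sensitivity = tp / (tp + fn) * 100,
    specificity = tn / (tn + fp) * 100,
    accuracy = (tp + tn) / (tp + fp + tn + fn) * 100)
}

#' Confusion counts for a subnetwork against a positive gene set
#'
#' TP/FP are counted inside the subnetwork against `positives`. TN/FN come
#' from the rest of the network adjusted to the subnetwork's size: a
#' uniform random sample (fixed `seed`) of as many genes as the subnetwork
#' holds, drawn from the network genes outside it; sampled positives count
#' as FN, the rest as TN. The counts are then rescaled to per-hundred
#' ([rescale_confusion()]).
#'
#' @param sub a `subnetwork` (see [snbuilder_extract()]).
#' @param positives character vector of genes assumed positive.
#' @param net the parent `edge_list`.
#' @param seed RNG seed for the complement sample.
#' @return rescaled `confusion_counts`.
#' @export
evaluate_subnetwork <- function(sub, positives, net, seed = 1L) {
  nodes <- sub$nodes
  all_genes <- sort(unique(c(net$from, net$to)))
  complement <- setdiff(all_genes, nodes)
  if (length(complement) < length(nodes)) {
    stop("network complement (", length(complement),
         " genes) is smaller than the subnetwork (", length(nodes), ")",
         call. = FALSE)
  }
  tp <- sum(nodes %in% positives)
  fp <- length(nodes) - tp
  sampled <- with_seed(seed, sample(complement, length(nodes)))
  fn <- sum(sampled %in% positives)
  tn <- length(sampled) - fn
  if (tp + fn == 0) {
    stop("no positive gene in subnetwork or complement sample", call. = FALSE)
  }
  rescale_confusion(confusion_counts(tp, fp, tn, fn))
}
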
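# Evaluation metrics and annotation-consensus utilities.
#
# Count-based metrics (accuracy, precision, recall, F1) follow the standard
# confusion-count formulas per label and are macro-averaged by default;
# score-based metrics (average precision / mAP, ROC AUC) operate on raw
# scores. Consensus curation keeps a sample only when all three annotators
# agree exactly; Cohen's kappa quantifies pairwise chance-corrected
# agreement.

#' Confusion-count classification metrics
#'
#' Per-label \eqn{Acc=(TP+TN)/(TP+TN+FP+FN)}, \eqn{P=TP/(TP+FP)},
#' \eqn{R=TP/(TP+FN)}, \eqn{F1=2PR/(P+R)}; zero-denominator cells yield 0
#' and are flagged.
#'
#' @param counts data.frame/matrix with columns `TP`, `TN`, `FP`, `FN`
#'   (one row per label), or a single named vector.
#' @param averaging `"macro"` (mean of per-label metrics) or `"micro"`
#'   (metrics of summed counts).
#' @return List with `acc`, `precision`, `recall`, `f1`, `per_label`
#'   (data.frame), and `degenerate` (logical: any zero-denominator cell).
#' @export
classificationMetrics <- function(counts, averaging = c("macro", "micro")) {
  averaging <- match.arg(averaging)
  if (is.null(dim(counts))) counts <- as.data.frame(as.list(counts))
  counts <- as.data.frame(counts)
  stopifnot(all(c("TP", "TN", "FP", "FN") %in% names(counts)))
  if (averaging == "micro")
    counts <- as.data.frame(as.list(colSums(counts[c("TP", "TN", "FP", "FN")])))
  sdiv <- function(num, den) ifelse(den > 0, num / den, 0)
  with_ <- counts
  acc <- sdiv(with_$TP + with_$TN, with_$TP + with_$TN + with_$FP + with_$FN)
  p <- sdiv(with_$TP, with_$TP + with_$FP)
  r <- sdiv(with_$TP, with_$TP + with_$FN)
  f1 <- sdiv(2 * p * r, p + r)
  degen <- any(with_$TP + with_$FP == 0) || any(with_$TP + with_$FN == 0) ||
    any(p + r == 0)
  per <- data.frame(acc = acc, precision = p, recall = r, f1 = f1)
  list(acc = mean(acc), precision = mean(p), recall = mean(r), f1 = mean(f1),
       per_label = per, degenerate = degen)
}

confusion_counts <- function(pred, truth) {
  # pred, truth: binary matrices (samples x labels) -> per-label counts
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  data.frame(
    TP = colSums(pred == 1 & truth == 1),
    TN = colSums(pred == 0 & truth == 0),
    FP = colSums(pred == 1 & truth == 0),
    FN = colSums(pred == 0 & truth == 1)
  )
}

#' Average precision of one ranked class
#'
#' Area under the precision-recall step curve: mean over positives of the
#' precision at each positive's rank (ties broken by stable order of the
#' sorted scores).
#'
#' @param scores numeric prediction scores.
#' @param targets binary ground truth, same length.
#' @return AP in `[0, 1]`; `NA` (with a warning) when the class has no
#'   positives.
#' @export
averagePrecision <- function(scores, targets) {
  stopifnot(length(scores) == length(targets))
  npos <- sum(targets == 1)
  if (npos == 0) {
    warning("no positives for this class; AP undefined (NA)")
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  t_sorted <- targets[ord]
  cum_tp <- cumsum(t_sorted)
  prec <- cum_tp / seq_along(t_sorted)
  sum(prec[t_sorted == 1]) / npos
}

#' Mean average precision over classes
#'
#' \eqn{mAP = \frac{1}{N}\sum_i AP_i}, the unweighted mean over classes;
#' classes without positives are skipped (flagged by a warning from
#' [averagePrecision()]).
#'
#' @param scores matrix (samples x classes) of scores, or a numeric vector
#'   of per-class APs.
#' @param targets binary matrix matching `scores` (omit when passing APs).
#' @return mAP in `[0, 1]`.
#' @export
mapScore <- function(scores, targets = NULL) {
  if (is.null(targets)) return(mean(scores, na.rm = TRUE))
  aps <- vapply(seq_len(ncol(scores)), function(j)
    suppressWarnings(averagePrecision(scores[, j], targets[, j])), numeric(1))
  if (all(is.na(aps))) stop("no positives in any class")
  mean(aps, na.rm = TRUE)
}

#' ROC AUC
#'
#' Trapezoidal area under the ROC curve; equals the Mann-Whitney
#' concordance probability (ties counted 1/2).
#'
#' @param scores numeric scores.
#' @param targets binary ground truth.
#' @return AUC in `[0, 1]`.
#' @export
aucScore <- function(scores, targets) {
  stopifnot(length(scores) == length(targets))
  pos <- scores[targets == 1]
  neg <- scores[targets == 0]
  if (length(pos) == 0 || length(neg) == 0)
    stop("aucScore: both classes must be present")
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Cohen's kappa
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' expected agreement from the product of marginals. For multi-label
#' matrices (samples x labels) kappa is computed per label and
#' macro-averaged.
#'
#' @param a,b categorical vectors (or binary label matrices) of equal size.
#' @return Kappa in `[-1, 1]`.
#' @export
cohensKappa <- function(a, b) {
  if (!is.null(dim(a))) {
    stopifnot(all(dim(a) == dim(b)))
    ks <- vapply(seq_len(ncol(a)), function(j) cohensKappa(a[, j], b[, j]),
                 numeric(1))
    return(mean(ks))
  }
  stopifnot(length(a) == length(b), length(a) >= 2L)
  lv <- sort(unique(c(a, b)))
  n <- length(a)
  po <- mean(a == b)
  pe <- sum(vapply(lv, function(v) mean(a == v) * mean(b == v), numeric(1)))
  if (pe == 1) {
    if (po == 1) return(1)
    stop("cohensKappa: expected agreement 1 with observed disagreement")
  }
  (po - pe) / (1 - pe)
}

#' Three-annotator consensus filter
#'
#' A sample is retained only when all three annotation vectors are exactly
#' identical; any discrepancy discards it.
#'
#' @param a1,a2,a3 label matrices (samples x labels) or vectors from the
#'   three annotators.
#' @return Logical vector, `TRUE` for retained samples.
#' @export
consensusFilter <- function(a1, a2, a3) {
  if (is.null(dim(a1))) { a1 <- matrix(a1, 1); a2 <- matrix(a2, 1); a3 <- matrix(a3, 1) }
  stopifnot(all(dim(a1) == dim(a2)), all(dim(a1) == dim(a3)))
  rowSums(a1 != a2) == 0 & rowSums(a1 != a3) == 0
}

#' Seeded audit subsample
#'
#' Draws \eqn{\lceil fraction \cdot n \rceil} ids without replacement for
#' manual review.
#'
#' @param ids vector of retained sample ids.
#' @param fraction fraction in `(0, 1]` (default 0.10).
#' @param seed integer RNG seed.
#' @return Subset of `ids`.
#' @export
auditSample <- function(ids, fraction = 0.10, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  if (length(ids) == 0L) return(ids[0])
  n <- ceiling(fraction * length(ids))
  set.seed(seed)
  ids[sample.int(length(ids), n)]
}

#' Full metric report for multi-label predictions
#'
#' @param scores matrix (samples x labels) of sigmoid scores.
#' @param truth binary matrix of targets.
#' @param threshold binarization threshold for count-based metrics.
#' @return List with `acc`, `precision`, `recall`, `f1`, `map`, `auc`
#'   (macro where applicable), plus `subset_acc` (exact-match rate over
#'   whole label vectors) and `per_label`.
#' @export
metricsReport <- function(scores, truth, threshold = 0.5) {
  pred <- (scores >= threshold) * 1
  cm <- classificationMetrics(confusion_counts(pred, truth))
  aucs <- vapply(seq_len(ncol(scores)), function(j) {
    if (length(unique(truth[, j])) < 2L) return(NA_real_)
    aucScore(scores[, j], truth[, j])
  }, numeric(1))
  list(acc = cm$acc, precision = cm$precision, recall = cm$recall,
       f1 = cm$f1,
       map = suppressWarnings(mapScore(scores, truth)),
       auc = mean(aucs, na.rm = TRUE),
       subset_acc = mean(rowSums(pred != truth) == 0),
       per_label = cm$per_label)
}
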
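# Threshold-sweep evaluation of aligner output against truth labels.
#
# A read counts as aligned at threshold t iff its distance is <= t (or
# >= t for score-like measures where higher is better, as with BLAST
# scores). Reads the aligner produced no distance for are treated as
# distance +Inf and are never aligned at any finite threshold.

#' @keywords internal
#' @noRd
check_labels <- function(labels) {
  if (!all(labels %in% c("positive", "negative"))) {
    stop("labels must be 'positive' or 'negative'", call. = FALSE)
  }
  invisible(NULL)
}

#' Confusion counts at one distance threshold
#'
#' @param distances numeric vector of per-read aligner distances (`NA` or
#'   `Inf` for reads with no alignment).
#' @param labels character vector, `"positive"`/`"negative"`, parallel to
#'   `distances`.
#' @param threshold acceptance threshold.
#' @param direction `"le"` (distance-like, aligned iff `<=`) or `"ge"`
#'   (score-like, aligned iff `>=`).
#' @return one-row data.frame: `threshold`, `TP`, `FP`, `FN`, `TN`,
#'   `precision` (`NA` when nothing aligns), `recall`, `TPR`, `FPR`.
#' @export
confusion_at_threshold <- function(distances, labels, threshold,
                                   direction = c("le", "ge")) {
  direction <- match.arg(direction)
  check_labels(labels)
  d <- ifelse(is.na(distances), Inf, distances)
  hit <- if (direction == "le") d <= threshold else d >= threshold
  pos <- labels == "positive"
  TP <- sum(hit & pos); FP <- sum(hit & !pos)
  FN <- sum(!hit & pos); TN <- sum(!hit & !pos)
  precision <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  recall <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  FPR <- if (FP + TN > 0) FP / (FP + TN) else NA_real_
  data.frame(threshold = threshold, TP = TP, FP = FP, FN = FN, TN = TN,
             precision = precision, recall = recall, TPR = recall,
             FPR = FPR)
}

#' Precision-recall / ROC curve over all observed thresholds
#'
#' One point per distinct observed distance (an observed-value sweep
#' dominates any fixed grid pointwise), plus a sentinel below the smallest
#' distance at which nothing aligns.
#'
#' @inheritParams confusion_at_threshold
#' @return data.frame of [confusion_at_threshold()] rows, thresholds
#'   ascending (descending for `direction = "ge"`).
#' @export
pr_curve <- function(distances, labels, direction = c("le", "ge")) {
  direction <- match.arg(direction)
  check_labels(labels)
  d <- ifelse(is.na(distances), Inf, distances)
  th <- sort(unique(d), decreasing = (direction == "ge"))
  finite <- d[is.finite(d)]
  sentinel <- if (direction == "le") {
    if (length(finite)) min(finite) - 1 else -1
  } else {
    if (length(finite)) max(finite) + 1 else 1
  }
  th <- c(sentinel, th)
  do.call(rbind, lapply(th, function(t)
    confusion_at_threshold(d, labels, t, direction)))
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of TPR over FPR across the observed-threshold
#' sweep; ties (equal distances for positives and negatives) contribute
#' diagonal segments, so the value equals the Mann-Whitney pair-counting
#' statistic (wins + half-ties over all positive-negative pairs).
#'
#' @inheritParams confusion_at_threshold
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(distances, labels, direction = c("le", "ge")) {
  direction <- match.arg(direction)
  check_labels(labels)
  if (!any(labels == "positive") || !any(labels == "negative")) {
    stop("AUC requires at least one positive and one negative", call. = FALSE)
  }
  curve <- pr_curve(distances, labels, direction)
  fpr <- c(curve$FPR, 1); tpr <- c(curve$TPR, 1)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' F-beta measure
#'
#' `(1 + beta^2) * P * R / (beta^2 * P + R)`, the weighted harmonic mean
#' of precision and recall; `beta = 2` weights recall higher. Returns 0
#' when `P = R = 0` (convention).
#'
#' @param precision,recall values in `[0, 1]` (vectorised).
#' @param beta positive weight.
#' @return F-beta value(s).
#' @export
f_beta <- function(precision, recall, beta = 1) {
  stopifnot(beta > 0)
  if (any(precision < 0 | precision > 1 | recall < 0 | recall > 1,
          na.rm = TRUE)) {
    stop("precision and recall must lie in [0, 1]", call. = FALSE)
  }
  den <- beta^2 * precision + recall
  ifelse(is.na(precision) | is.na(recall) | den == 0, 0,
         (1 + beta^2) * precision * recall / den)
}

#' Best F-beta score along a curve
#'
#' @param curve a [pr_curve()] data.frame.
#' @param beta positive weight.
#' @return the maximum F-beta over the curve's points (undefined-precision
#'   points count as 0).
#' @export
best_f_beta <- function(curve, beta = 1) {
  max(f_beta(curve$precision, curve$recall, beta))
}

#' Recall at the curve's best precision
#'
#' Among the points attaining the maximal precision, returns the maximal
#' recall together with that precision. Points where nothing aligns
#' (undefined precision) are ignored; if no point aligns anything, both
#' values are 0.
#'
#' @param curve a [pr_curve()] data.frame.
#' @return list with `recall` and `precision`.
#' @export
recall_at_best_precision <- function(curve) {
  ok <- !is.na(curve$precision)
  if (!any(ok)) return(list(recall = 0, precision = 0))
  best_p <- max(curve$precision[ok])
  at <- ok & curve$precision == best_p
  list(recall = max(curve$recall[at]), precision = best_p)
}

#' Maximum recall attained anywhere on a curve
#'
#' @param curve a [pr_curve()] data.frame.
#' @return the largest recall.
#' @export
max_recall <- function(curve) {
  max(c(0, curve$recall), na.rm = TRUE)
}

#' Sequence-distance summaries of mapped versus unmapped positive reads
#'
#' At a given threshold, positive reads are split into mapped (true
#' positives, distance `<=` threshold) and unmapped (false negatives);
#' for each side the count and the mean Hamming and edit distances between
#' each read and the genome substring it was simulated from are reported
#' (reverse-complement reads are re-complemented before comparison).
#' Means are `NA` when a side is empty.
#'
#' @param sim_reads a [simulate_reads()]-style data.frame (columns `read`,
#'   `strand`, `truth`) restricted to positive reads.
#' @param distances aligner distances parallel to `sim_reads` rows.
#' @param threshold acceptance threshold.
#' @return one-row data.frame: `threshold`, `TP`, `FN`, `tp_hamming`,
#'   `fn_hamming`, `tp_edit`, `fn_edit`.
#' @export
tp_fn_distance_metrics <- function(sim_reads, distances, threshold) {
  stopifnot(all(c("read", "strand", "truth") %in% names(sim_reads)),
            nrow(sim_reads) == length(distances))
  fwd <- ifelse(sim_reads$strand == "-",
                vapply(sim_reads$read, reverse_complement, character(1L)),
                sim_reads$read)
  ham <- mapply(hamming_distance, fwd, sim_reads$truth)
  edt <- mapply(edit_distance, fwd, sim_reads$truth)
  d <- ifelse(is.na(distances), Inf, distances)
  tp <- d <= threshold
  side_mean <- function(v, sel) if (any(sel)) mean(v[sel]) else NA_real_
  data.frame(threshold = threshold, TP = sum(tp), FN = sum(!tp),
             tp_hamming = side_mean(ham, tp),
             fn_hamming = side_mean(ham, !tp),
             tp_edit = side_mean(edt, tp),
             fn_edit = side_mean(edt, !tp))
}
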
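#' Match one frame's predicted boxes to ground truth
#'
#' Optimal (Hungarian) matching that maximises total IoU over pairs with
#' IoU at or above the threshold. Matched pairs are true positives,
#' unmatched predictions false positives, unmatched ground-truth boxes
#' false negatives.
#'
#' @param gt_boxes,pred_boxes Data frames with columns `x`, `y`, `w`, `h`
#'   (one frame's boxes).
#' @param iou_threshold Minimum IoU for a pair to count as a match
#'   (default 0.5).
#' @return A list with `counts` (named integer vector `TP`, `FP`, `FN`)
#'   and `matches` (two-column matrix of gt row / pred row indices).
#' @export
match_frame <- function(gt_boxes, pred_boxes, iou_threshold = 0.5) {
  gt_boxes <- as.data.frame(gt_boxes); pred_boxes <- as.data.frame(pred_boxes)
  iou <- bbox_iou_matrix(gt_boxes, pred_boxes)
  res <- gated_assignment(-iou, feasible = iou >= iou_threshold)
  tp <- nrow(res$matches)
  list(counts = c(TP = tp, FP = nrow(pred_boxes) - tp,
                  FN = nrow(gt_boxes) - tp),
       matches = res$matches)
}

undefined_metric <- function(what) {
  warning(warningCondition(paste0(what, " is undefined (zero denominator)"),
                           class = "herdtrack_undefined_metric"))
  NA_real_
}

#' Precision, recall and F1 from confusion counts
#'
#' `Recall = TP / (TP + FN)`, `Precision = TP / (TP + FP)`,
#' `F1 = 2 TP / (2 TP + FP + FN)`. A ratio whose denominator is zero is
#' undefined: it is returned as `NA` with a
#' `herdtrack_undefined_metric` warning rather than a silent zero, so that
#' degenerate frames cannot corrupt aggregate tables unnoticed.
#'
#' @param counts Named vector or list with elements `TP`, `FP`, `FN`.
#' @return Named numeric vector `precision`, `recall`, `f1`.
#' @examples
#' prf(c(TP = 8, FP = 2, FN = 2))  # 0.8, 0.8, 0.8
#' @export
prf <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  fn <- as.numeric(counts[["FN"]])
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else undefined_metric("precision")
  recall <- if (tp + fn > 0) tp / (tp + fn) else undefined_metric("recall")
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn)
        else undefined_metric("F1")
  c(precision = precision, recall = recall, f1 = f1)
}

#' Average precision at one IoU threshold
#'
#' Confidence-descending sweep with the conventional greedy assignment:
#' each prediction, taken in decreasing confidence order, claims the
#' still-unclaimed ground-truth box in its frame with the highest IoU at
#' or above the threshold. The precision-recall curve is integrated with
#' all-points interpolation (precision envelope summed over recall
#' increments). Depends on confidences only through their ranking.
#'
#' @param pred Data frame of predictions: `frame`, `x`, `y`, `w`, `h`,
#'   `conf`.
#' @param gt Data frame of ground truth: `frame`, `x`, `y`, `w`, `h`.
#' @param iou_threshold IoU required for a prediction to claim a
#'   ground-truth box.
#' @return AP in `[0, 1]`; `NA` (with warning) when `gt` is empty.
#' @export
average_precision <- function(pred, gt, iou_threshold = 0.5) {
  pred <- as.data.frame(pred); gt <- as.data.frame(gt)
  if (nrow(gt) == 0L) return(undefined_metric("average precision"))
  if (nrow(pred) == 0L) return(0)
  ord <- order(-pred$conf, pred$frame)
  pred <- pred[ord, , drop = FALSE]
  gt$.claimed <- FALSE
  tp <- logical(nrow(pred))
  for (i in seq_len(nrow(pred))) {
    cand <- which(gt$frame == pred$frame[i] & !gt$.claimed)
    if (!length(cand)) next
    ious <- bbox_iou_matrix(gt[cand, , drop = FALSE],
                            pred[i, , drop = FALSE])[, 1]
    j <- which.max(ious)
    if (ious[j] >= iou_threshold) {
      tp[i] <- TRUE
      gt$.claimed[cand[j]] <- TRUE
    }
  }
  cum_tp <- cumsum(tp)
  recall <- cum_tp / nrow(gt)
  precision <- cum_tp / seq_along(tp)
  # all-points interpolation: running max of precision from the right
  prec_env <- rev(cummax(rev(precision)))
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * prec_env)
}

#' Mean average precision over classes and IoU thresholds
#'
#' AP is computed per class at each threshold and averaged, first over
#' classes then over thresholds. The default threshold grid
#' `0.50, 0.55, ..., 0.95` gives the COCO-style mAP\@0.5:0.95; a single
#' threshold of 0.5 gives mAP\@0.5. Classes absent from the ground truth
#' are excluded with a warning.
#'
#' @param pred Predictions with columns `frame`, `x`, `y`, `w`, `h`,
#'   `conf` and optionally `class` (single class assumed when absent).
#' @param gt Ground truth with columns `frame`, `x`, `y`, `w`, `h` and
#'   optionally `class`.
#' @param iou_thresholds Numeric vector of IoU thresholds.
#' @return A list with `map`, `per_class` (AP per class averaged over
#'   thresholds), and `per_threshold`.
#' @export
map_detections <- function(pred, gt,
                           iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  pred <- as.data.frame(pred); gt <- as.data.frame(gt)
  if (!"class" %in% names(pred)) pred$class <- 0L
  if (!"class" %in% names(gt)) gt$class <- 0L
  classes <- sort(unique(gt$class))
  orphan <- setdiff(unique(pred$class), classes)
  if (length(orphan))
    warning("classes with predictions but no ground truth excluded: ",
            paste(orphan, collapse = ", "))
  ap <- matrix(NA_real_, length(classes), length(iou_thresholds),
               dimnames = list(as.character(classes), NULL))
  for (ci in seq_along(classes)) {
    gc <- gt[gt$class == classes[ci], , drop = FALSE]
    pc <- pred[pred$class == classes[ci], , drop = FALSE]
    for (ti in seq_along(iou_thresholds))
      ap[ci, ti] <- average_precision(pc, gc, iou_thresholds[ti])
  }
  list(map = mean(ap),
       per_class = rowMeans(ap),
       per_threshold = colMeans(ap),
       iou_thresholds = iou_thresholds)
}
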
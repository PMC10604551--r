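#' Greedy matching of detections to ground truth
#'
#' Detections are processed in descending score order (deterministic
#' tie-break by `(cy, cx, r)`); each is matched to the not-yet-matched
#' ground-truth circle of the same class with the highest circle IoU at or
#' above `iou_thresh`.
#'
#' @param dets detection data frame (`cx`, `cy`, `r`, `class_id`, `score`).
#' @param gts ground-truth data frame (`cx`, `cy`, `r`, `class_id`).
#' @param iou_thresh minimum IoU for a match (default 0.5).
#' @param iou_fun IoU convention, [circle_iou()] by default (use
#'   [circle_box_iou()] for the rectangle convention).
#' @return `dets` sorted by descending score with extra columns `gt` (matched
#'   ground-truth row index, `NA` for false positives) and `iou`.
#' @export
match_detections <- function(dets, gts, iou_thresh = 0.5, iou_fun = circle_iou) {
  if (is.null(dets$class_id)) dets$class_id <- 1L
  if (nrow(gts) > 0 && is.null(gts$class_id)) gts$class_id <- 1L
  if (nrow(dets) == 0) {
    dets$gt <- integer(0); dets$iou <- numeric(0)
    return(dets)
  }
  dets <- dets[order_detections(dets), , drop = FALSE]
  rownames(dets) <- NULL
  dets$gt <- NA_integer_
  dets$iou <- 0
  taken <- rep(FALSE, nrow(gts))
  for (i in seq_len(nrow(dets))) {
    cand <- which(!taken & gts$class_id == dets$class_id[i])
    if (length(cand) == 0) next
    ious <- iou_fun(dets[i, , drop = FALSE], gts[cand, , drop = FALSE])
    j <- which.max(ious)
    if (ious[j] >= iou_thresh) {
      dets$gt[i] <- cand[j]
      dets$iou[i] <- ious[j]
      taken[cand[j]] <- TRUE
    }
  }
  dets
}

# PR points from per-image matching, pooled across the evaluation set.
# `dets`/`gts` carry a `file` column identifying the image.
pooled_matches <- function(dets, gts, iou_thresh, iou_fun = circle_iou) {
  files <- unique(c(dets$file, gts$file))
  out <- vector("list", length(files))
  for (k in seq_along(files)) {
    d <- dets[dets$file == files[k], , drop = FALSE]
    g <- gts[gts$file == files[k], , drop = FALSE]
    m <- match_detections(d, g, iou_thresh, iou_fun)
    out[[k]] <- m
  }
  do.call(rbind, out)
}

#' Average precision of a detection set
#'
#' Pools detections across the evaluation set, matches them greedily per
#' image, accumulates TP/FP in descending score order and integrates the
#' precision-recall curve. The default is the all-point interpolation (area
#' under the precision envelope); `interpolation = "11point"` gives the
#' legacy 11-point average.
#'
#' @param dets detections with a `file` column (image id) plus circle
#'   columns and `score`.
#' @param gts ground truth with a `file` column.
#' @param iou_thresh match threshold on circle IoU (default 0.5).
#' @param interpolation `"all"` (default) or `"11point"`.
#' @param iou_fun IoU convention (default [circle_iou()]).
#' @return AP in `[0, 1]`; `NA` with a warning if there is no ground truth.
#' @export
average_precision <- function(dets, gts, iou_thresh = 0.5,
                              interpolation = c("all", "11point"),
                              iou_fun = circle_iou) {
  interpolation <- match.arg(interpolation)
  n_gt <- nrow(gts)
  if (n_gt == 0) {
    warning("no ground-truth circles: AP undefined")
    return(NA_real_)
  }
  if (nrow(dets) == 0) return(0)
  m <- pooled_matches(dets, gts, iou_thresh, iou_fun)
  m <- m[order(-m$score, m$cy, m$cx, m$r), , drop = FALSE]
  tp <- cumsum(!is.na(m$gt))
  fp <- cumsum(is.na(m$gt))
  recall <- tp / n_gt
  precision <- tp / (tp + fp)
  if (interpolation == "11point") {
    return(mean(vapply(seq(0, 1, 0.1), function(rr) {
      ok <- recall >= rr
      if (!any(ok)) 0 else max(precision[ok])
    }, numeric(1))))
  }
  # all-point: area under the precision envelope
  r_pts <- c(0, recall)
  p_env <- rev(cummax(rev(precision)))
  sum((recall - r_pts[-length(r_pts)]) * p_env)
}

#' Mean average precision over classes
#'
#' @param per_class_ap numeric vector of per-class AP values; `NA` entries
#'   (classes without ground truth) are dropped with a warning.
#' @return The arithmetic mean of the defined per-class APs.
#' @export
mean_ap <- function(per_class_ap) {
  if (any(is.na(per_class_ap))) {
    warning("dropping classes with undefined AP from the mean")
    per_class_ap <- per_class_ap[!is.na(per_class_ap)]
  }
  if (length(per_class_ap) == 0) stop("no class has a defined AP")
  mean(per_class_ap)
}

#' Image-level label from detections
#'
#' An image is called positive iff it has at least one detection with score
#' at or above `tau`.
#'
#' @param dets detections for one image.
#' @param tau score threshold (default 0.5).
#' @return `"positive"` or `"negative"`.
#' @export
classify_image <- function(dets, tau = 0.5) {
  if (!is.null(dets) && nrow(dets) > 0 && any(dets$score >= tau))
    "positive" else "negative"
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall and F1 (harmonic mean of precision and
#' recall). Metrics with a zero denominator are reported as `NA` with a
#' warning rather than 0.
#'
#' @param tp,tn,fp,fn confusion-matrix counts.
#' @return Named list with `accuracy`, `precision`, `recall`, `f1` and the
#'   counts.
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  total <- tp + tn + fp + fn
  safe_div <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (zero denominator)"); return(NA_real_) }
    num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (is.na(precision) || is.na(recall)) NA_real_
        else if (precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  list(accuracy = safe_div(tp + tn, total, "accuracy"),
       precision = precision, recall = recall, f1 = f1,
       tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Evaluate predictions against ground truth
#'
#' Produces the full evaluation report: per-class AP and mAP at a circle-IoU
#' threshold, mean matched IoU, and image-level classification metrics
#' (an image is predicted positive iff any detection scores >= `tau`;
#' it is truly positive iff it has ground-truth circles).
#'
#' @param preds detection data frame with `file` column.
#' @param gts ground-truth data frame with `file` column.
#' @param images character vector of all evaluated image ids (needed so
#'   images with neither detections nor ground truth count as true
#'   negatives); defaults to the union of the `file` columns.
#' @param iou_thresh match threshold (default 0.5).
#' @param tau image-level score threshold (default 0.5).
#' @param interpolation AP interpolation, see [average_precision()].
#' @param iou_fun IoU convention (default [circle_iou()]).
#' @param out_json optional path to write the report as JSON.
#' @return List of class `eval_report`.
#' @export
evaluate_predictions <- function(preds, gts, images = NULL, iou_thresh = 0.5,
                                 tau = 0.5, interpolation = "all",
                                 iou_fun = circle_iou, out_json = NULL) {
  if (is.null(images)) images <- unique(c(preds$file, gts$file))
  if (is.null(preds$class_id) && nrow(preds)) preds$class_id <- 1L
  if (is.null(gts$class_id) && nrow(gts)) gts$class_id <- 1L
  classes <- sort(unique(c(preds$class_id, gts$class_id)))
  if (length(classes) == 0) classes <- 1L

  per_class <- setNames(numeric(length(classes)), paste0("class_", classes))
  for (k in seq_along(classes)) {
    dc <- preds[preds$class_id == classes[k], , drop = FALSE]
    gc <- gts[gts$class_id == classes[k], , drop = FALSE]
    per_class[k] <- if (nrow(gc) == 0) NA_real_ else
      average_precision(dc, gc, iou_thresh, interpolation, iou_fun)
  }
  map_score <- mean_ap(per_class)

  m <- pooled_matches(preds, gts, iou_thresh, iou_fun)
  matched <- m[!is.na(m$gt), , drop = FALSE]
  mean_iou <- if (nrow(matched)) mean(matched$iou) else NA_real_

  tp <- tn <- fp <- fn <- 0L
  for (f in images) {
    pred_pos <- classify_image(preds[preds$file == f, , drop = FALSE], tau) == "positive"
    true_pos <- sum(gts$file == f) > 0
    if (pred_pos && true_pos) tp <- tp + 1L
    else if (pred_pos && !true_pos) fp <- fp + 1L
    else if (!pred_pos && true_pos) fn <- fn + 1L
    else tn <- tn + 1L
  }
  cls <- classification_metrics(tp, tn, fp, fn)

  report <- c(list(per_class_ap = as.list(per_class), map = map_score,
                   mean_matched_iou = mean_iou,
                   iou_thresh = iou_thresh, tau = tau,
                   n_images = length(images)),
              cls)
  class(report) <- "eval_report"
  if (!is.null(out_json))
    jsonlite::write_json(unclass(report), out_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat("circle detection evaluation (", x$n_images, " images)\n", sep = "")
  cat(sprintf("  mAP@cIoU%.2f: %.4f   mean matched IoU: %.4f\n",
              x$iou_thresh, x$map, x$mean_matched_iou))
  cat(sprintf("  accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}
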
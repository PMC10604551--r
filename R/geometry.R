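#' Circle constructors and validation
#'
#' A circle is parameterised by a continuous centre `(cx, cy)` in 0-based
#' input-pixel coordinates (x = column, y = row) and a radius `r >= 0`.
#' Sets of circles are stored as data frames with columns `cx`, `cy`, `r`
#' plus optional `class_id` (1-based integer) and `score`.
#'
#' @param cx,cy,r numeric vectors (recycled) of centres and radii.
#' @param class_id optional 1-based integer class labels.
#' @param score optional detection scores in `[0, 1]`.
#' @return A data frame with one row per circle.
#' @examples
#' circles(cx = c(10, 40), cy = c(10, 40), r = c(5, 8))
#' @export
circles <- function(cx, cy, r, class_id = NULL, score = NULL) {
  d <- data.frame(cx = as.numeric(cx), cy = as.numeric(cy), r = as.numeric(r))
  if (!is.null(class_id)) d$class_id <- as.integer(class_id)
  if (!is.null(score)) d$score <- as.numeric(score)
  validate_circles(d)
  d
}

validate_circles <- function(d) {
  stopifnot(is.data.frame(d), all(c("cx", "cy", "r") %in% names(d)))
  if (nrow(d) == 0) return(invisible(d))
  if (!all(is.finite(d$cx)) || !all(is.finite(d$cy)) || !all(is.finite(d$r)))
    stop("circle coordinates must be finite")
  if (any(d$r < 0)) stop("circle radii must be >= 0")
  if (!is.null(d$score) && (any(d$score < 0) || any(d$score > 1)))
    stop("scores must lie in [0, 1]")
  invisible(d)
}

#' Area of circles
#'
#' @param x a circle data frame (see [circles()]) or a numeric radius vector.
#' @return Numeric vector of areas `pi * r^2` in pixel^2.
#' @examples
#' circle_area(circles(0, 0, 2)) # 4 * pi
#' @export
circle_area <- function(x) {
  r <- if (is.data.frame(x)) x$r else as.numeric(x)
  pi * r^2
}

#' Exact intersection area of two circles
#'
#' Computes the lens-shaped overlap analytically: 0 for disjoint circles,
#' the smaller disk's area when one circle contains the other, and the sum
#' of the two circular-segment areas otherwise.
#'
#' @param a,b circle data frames; rows are paired (recycled to equal length).
#' @return Numeric vector of intersection areas in pixel^2.
#' @examples
#' a <- circles(0, 0, 1); b <- circles(1, 0, 1)
#' circle_intersection_area(a, b) # ~ 1.2284
#' @export
circle_intersection_area <- function(a, b) {
  intersect_area_num(a$cx, a$cy, a$r, b$cx, b$cy, b$r)
}

intersect_area_num <- function(ax, ay, ar, bx, by, br) {
  n <- max(length(ax), length(bx))
  ax <- rep_len(ax, n); ay <- rep_len(ay, n); ar <- rep_len(ar, n)
  bx <- rep_len(bx, n); by <- rep_len(by, n); br <- rep_len(br, n)
  d <- sqrt((ax - bx)^2 + (ay - by)^2)
  out <- numeric(n)
  contained <- d <= abs(ar - br)
  out[contained] <- pi * pmin(ar, br)[contained]^2
  partial <- !contained & d < ar + br & ar > 0 & br > 0
  if (any(partial)) {
    dd <- d[partial]; r1 <- ar[partial]; r2 <- br[partial]
    # clamp acos arguments against roundoff at tangency
    a1 <- pmin(1, pmax(-1, (dd^2 + r1^2 - r2^2) / (2 * dd * r1)))
    a2 <- pmin(1, pmax(-1, (dd^2 + r2^2 - r1^2) / (2 * dd * r2)))
    t <- pmax(0, (-dd + r1 + r2) * (dd + r1 - r2) * (dd - r1 + r2) * (dd + r1 + r2))
    out[partial] <- r1^2 * acos(a1) + r2^2 * acos(a2) - 0.5 * sqrt(t)
  }
  out
}

#' Circle intersection-over-union
#'
#' IoU of two disks from the exact lens intersection area:
#' `I / (area(a) + area(b) - I)`. Two degenerate (zero-radius) circles have
#' IoU 0 by convention.
#'
#' @inheritParams circle_intersection_area
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @examples
#' circle_iou(circles(0, 0, 2), circles(0, 0, 1)) # 0.25
#' @export
circle_iou <- function(a, b) {
  iou_num(a$cx, a$cy, a$r, b$cx, b$cy, b$r)
}

iou_num <- function(ax, ay, ar, bx, by, br) {
  inter <- intersect_area_num(ax, ay, ar, bx, by, br)
  uni <- pi * rep_len(ar, length(inter))^2 + pi * rep_len(br, length(inter))^2 - inter
  ifelse(uni <= 0, 0, inter / uni)
}

#' Box-convention IoU of circles
#'
#' IoU of the axis-aligned squares bounding each circle (side `2r`), for
#' comparison with rectangle-based detectors. [circle_iou()] is the package
#' default everywhere a threshold is applied.
#'
#' @inheritParams circle_intersection_area
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @export
circle_box_iou <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ax <- rep_len(a$cx, n); ay <- rep_len(a$cy, n); ar <- rep_len(a$r, n)
  bx <- rep_len(b$cx, n); by <- rep_len(b$cy, n); br <- rep_len(b$r, n)
  ix <- pmax(0, pmin(ax + ar, bx + br) - pmax(ax - ar, bx - br))
  iy <- pmax(0, pmin(ay + ar, by + br) - pmax(ay - ar, by - br))
  inter <- ix * iy
  uni <- (2 * ar)^2 + (2 * br)^2 - inter
  ifelse(uni <= 0, 0, inter / uni)
}

# IoU matrix between two circle sets (rows of a x rows of b), one class.
iou_matrix <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(matrix(0, nrow(a), nrow(b)))
  outer(seq_len(nrow(a)), seq_len(nrow(b)),
        function(i, j) iou_num(a$cx[i], a$cy[i], a$r[i], b$cx[j], b$cy[j], b$r[j]))
}

# Deterministic detection ordering: score desc, ties by (cy, cx, r).
order_detections <- function(d) {
  order(-d$score, d$cy, d$cx, d$r)
}

#' Greedy non-maximum suppression for circle detections
#'
#' Detections are visited in descending score order (ties broken by
#' `(cy, cx, r)` so the result is independent of input order); a detection is
#' kept iff its circle IoU with every already-kept detection of the same
#' class is below `iou_thresh`.
#'
#' @param dets detection data frame (`cx`, `cy`, `r`, `class_id`, `score`).
#' @param iou_thresh suppression threshold in `[0, 1]` (default 0.5).
#' @return The kept detections, sorted by descending score.
#' @export
circle_nms <- function(dets, iou_thresh = 0.5) {
  if (is.null(dets) || nrow(dets) == 0) return(dets)
  validate_circles(dets)
  stopifnot(!is.null(dets$score))
  if (is.null(dets$class_id)) dets$class_id <- 1L
  dets <- dets[order_detections(dets), , drop = FALSE]
  n <- nrow(dets)
  keep <- logical(n)
  for (i in seq_len(n)) {
    kept_same <- which(keep & dets$class_id == dets$class_id[i])
    if (length(kept_same) == 0) { keep[i] <- TRUE; next }
    ious <- iou_num(dets$cx[i], dets$cy[i], dets$r[i],
                    dets$cx[kept_same], dets$cy[kept_same], dets$r[kept_same])
    keep[i] <- all(ious < iou_thresh)
  }
  out <- dets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
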
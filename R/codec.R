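#' Codec configuration
#'
#' Controls how ground-truth circles are encoded into training target maps
#' and how network outputs are decoded back into detections.
#'
#' @param stride integer down-sampling factor `R` between the input image and
#'   the output grid (default 4; must divide the image size).
#' @param num_classes number of foreground object classes (heatmap channels).
#' @param top_h maximum number of peaks retained per image (default 100).
#' @param score_threshold minimum peak score kept after ranking (default 0.3).
#' @param sigma_policy function mapping a radius in output-grid units to the
#'   Gaussian spread `sigma` (also in output-grid units). The default,
#'   `max(1, r_grid / 3)`, widens the bump for large cells so their centre
#'   tolerance scales with size.
#' @return An object of class `codec_config`.
#' @export
codec_config <- function(stride = 4L, num_classes = 1L, top_h = 100L,
                         score_threshold = 0.3,
                         sigma_policy = function(r_grid) pmax(1, r_grid / 3)) {
  stopifnot(stride >= 1, num_classes >= 1, top_h >= 1,
            score_threshold >= 0, score_threshold <= 1, is.function(sigma_policy))
  structure(list(stride = as.integer(stride), num_classes = as.integer(num_classes),
                 top_h = as.integer(top_h), score_threshold = score_threshold,
                 sigma_policy = sigma_policy),
            class = "codec_config")
}

#' Unnormalised Gaussian kernel value
#'
#' `exp(-sq_dist / (2 * sigma^2))`, the value a heatmap cell receives from a
#' keypoint at squared grid distance `sq_dist`.
#'
#' @param sq_dist squared distance (output-grid cells^2), `>= 0`.
#' @param sigma Gaussian spread in output-grid cells, `> 0`.
#' @return Values in `(0, 1]`.
#' @export
gaussian_value <- function(sq_dist, sigma) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  exp(-sq_dist / (2 * sigma^2))
}

#' Encode circle annotations into training target maps
#'
#' Each annotation of class `s` with centre `(cx, cy)` and radius `r` is
#' down-sampled by the stride `R`: its integer cell is
#' `(floor(cx / R), floor(cy / R))`. Heatmap channel `s` receives a Gaussian
#' bump centred on that cell (elementwise max with existing values, so the
#' map stays in `[0, 1]`); the offset map stores the fractional parts
#' `(cx / R - floor(cx / R), cy / R - floor(cy / R))`, the radius map stores
#' `r / R` (output-grid units), and the keypoint mask marks the cell.
#'
#' @param anns annotation data frame (`cx`, `cy`, `r`, optional `class_id`).
#' @param image_size integer `c(H, W)` of the input image.
#' @param cfg a [codec_config()].
#' @return A list of class `target_maps` with elements `heatmap`
#'   (`H/R x W/R x num_classes`), `offset` (`H/R x W/R x 2`, x then y),
#'   `radius` (`H/R x W/R`), `mask` (`H/R x W/R`, 0/1) and `n_keypoints`.
#' @export
encode_targets <- function(anns, image_size, cfg = codec_config()) {
  stopifnot(length(image_size) == 2)
  H <- as.integer(image_size[1]); W <- as.integer(image_size[2])
  R <- cfg$stride
  if (H %% R != 0 || W %% R != 0) stop("image size must be divisible by the stride")
  Ho <- H %/% R; Wo <- W %/% R
  maps <- list(heatmap = array(0, c(Ho, Wo, cfg$num_classes)),
               offset = array(0, c(Ho, Wo, 2)),
               radius = array(0, c(Ho, Wo)),
               mask = array(0, c(Ho, Wo)),
               n_keypoints = 0L)
  class(maps) <- "target_maps"
  if (is.null(anns) || nrow(anns) == 0) return(maps)
  validate_circles(anns)
  if (is.null(anns$class_id)) anns$class_id <- 1L
  bad <- which(anns$cx < 0 | anns$cx >= W | anns$cy < 0 | anns$cy >= H)
  if (length(bad))
    stop("annotation ", bad[1], " centre (", anns$cx[bad[1]], ", ", anns$cy[bad[1]],
         ") lies outside the ", H, "x", W, " image")
  if (any(anns$class_id < 1 | anns$class_id > cfg$num_classes))
    stop("class_id outside 1..num_classes")

  gx <- matrix(rep(0:(Wo - 1), each = Ho), Ho, Wo)  # cell x (column), 0-based
  gy <- matrix(rep(0:(Ho - 1), Wo), Ho, Wo)         # cell y (row), 0-based
  for (k in seq_len(nrow(anns))) {
    px <- anns$cx[k] / R; py <- anns$cy[k] / R
    u <- floor(px); v <- floor(py)                  # 0-based integer cell
    sig <- cfg$sigma_policy(anns$r[k] / R)
    bump <- gaussian_value((gx - u)^2 + (gy - v)^2, sig)
    s <- anns$class_id[k]
    maps$heatmap[, , s] <- pmax(maps$heatmap[, , s], bump)
    i <- v + 1L; j <- u + 1L
    if (maps$mask[i, j] == 1)
      warning("two annotations share output cell (", u, ", ", v,
              "); offset/radius of the later one kept")
    maps$offset[i, j, 1] <- px - u
    maps$offset[i, j, 2] <- py - v
    maps$radius[i, j] <- anns$r[k] / R
    maps$mask[i, j] <- 1
  }
  maps$n_keypoints <- nrow(anns)
  maps
}

# 8-neighbourhood local-maximum test, vectorised via shifted copies.
# Edge cells compare only against existing neighbours.
local_maxima <- function(m) {
  Ho <- nrow(m); Wo <- ncol(m)
  pad <- matrix(-Inf, Ho + 2, Wo + 2)
  pad[2:(Ho + 1), 2:(Wo + 1)] <- m
  is_max <- matrix(TRUE, Ho, Wo)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- pad[(2 + di):(Ho + 1 + di), (2 + dj):(Wo + 1 + dj)]
    is_max <- is_max & (m >= nb)
  }
  is_max
}

#' Extract ranked peaks from a heatmap
#'
#' A cell is a peak iff its value is greater than or equal to all of its
#' 8-connected neighbours (edge cells compare only the neighbours that
#' exist; plateaus keep every cell). Peaks from all classes are pooled,
#' ordered by descending score (ties by row then column), truncated to
#' `cfg$top_h` and then filtered by `cfg$score_threshold`.
#'
#' @param heatmap array `Ho x Wo x num_classes` (a matrix is taken as one class).
#' @param cfg a [codec_config()].
#' @return Data frame with 0-based cell coordinates `u` (column), `v` (row),
#'   `class_id` and `score`, sorted by descending score.
#' @export
extract_peaks <- function(heatmap, cfg = codec_config()) {
  if (is.matrix(heatmap)) heatmap <- array(heatmap, c(dim(heatmap), 1))
  S <- dim(heatmap)[3]
  out <- vector("list", S)
  for (s in seq_len(S)) {
    m <- heatmap[, , s]
    pk <- which(local_maxima(m), arr.ind = TRUE)
    out[[s]] <- data.frame(u = pk[, 2] - 1L, v = pk[, 1] - 1L,
                           class_id = s, score = m[pk])
  }
  pk <- do.call(rbind, out)
  pk <- pk[order(-pk$score, pk$v, pk$u, pk$class_id), , drop = FALSE]
  pk <- head(pk, cfg$top_h)
  pk <- pk[pk$score >= cfg$score_threshold, , drop = FALSE]
  rownames(pk) <- NULL
  pk
}

#' Decode network output maps into circle detections
#'
#' For every retained peak `(u, v, s)` the detection centre is
#' `((u + offset_x) * R, (v + offset_y) * R)`, the radius is
#' `radius_map[v, u] * R` (clamped at 0), the score is the heatmap value and
#' the class is the peak's channel.
#'
#' @param heatmap array `Ho x Wo x num_classes` of values in `[0, 1]`.
#' @param offset array `Ho x Wo x 2` (x then y fractional shifts).
#' @param radius matrix `Ho x Wo` of radii in output-grid units.
#' @param cfg a [codec_config()].
#' @param nms apply [circle_nms()] to the decoded list (default `TRUE`).
#' @param nms_thresh suppression threshold (default 0.5).
#' @return Detection data frame (`cx`, `cy`, `r`, `class_id`, `score`),
#'   scores non-increasing.
#' @export
decode_detections <- function(heatmap, offset, radius, cfg = codec_config(),
                              nms = TRUE, nms_thresh = 0.5) {
  if (is.matrix(heatmap)) heatmap <- array(heatmap, c(dim(heatmap), 1))
  if (length(dim(radius)) == 3) radius <- radius[, , 1]
  stopifnot(all(dim(heatmap)[1:2] == dim(offset)[1:2]),
            all(dim(heatmap)[1:2] == dim(radius)[1:2]))
  pk <- extract_peaks(heatmap, cfg)
  R <- cfg$stride
  if (nrow(pk) == 0)
    return(data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0),
                      class_id = integer(0), score = numeric(0)))
  i <- pk$v + 1L; j <- pk$u + 1L
  lin <- cbind(i, j)
  dets <- data.frame(
    cx = (pk$u + offset[cbind(i, j, 1L)]) * R,
    cy = (pk$v + offset[cbind(i, j, 2L)]) * R,
    r = pmax(0, radius[lin]) * R,
    class_id = pk$class_id,
    score = pk$score)
  if (nms) dets <- circle_nms(dets, nms_thresh)
  rownames(dets) <- NULL
  dets
}
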
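#' Loss weights and focal-loss hyper-parameters
#'
#' The total objective is `L = Lh + lambda_r * Lr + lambda_o * Lo` with the
#' penalty-reduced focal heatmap loss `Lh` (exponents `alpha`, `beta`), the
#' L1 radius loss `Lr` and the L1 offset loss `Lo`.
#'
#' @param lambda_r weight of the radius loss (default 0.1).
#' @param lambda_o weight of the offset loss (default 1).
#' @param alpha focal exponent on the prediction (default 2).
#' @param beta penalty-reduction exponent on the Gaussian target (default 4).
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_r = 0.1, lambda_o = 1, alpha = 2, beta = 4) {
  stopifnot(lambda_r >= 0, lambda_o >= 0, alpha >= 0, beta >= 0)
  structure(list(lambda_r = lambda_r, lambda_o = lambda_o,
                 alpha = alpha, beta = beta), class = "loss_weights")
}

#' Penalty-reduced focal heatmap loss
#'
#' Pixel-wise focal loss over all heatmap cells and classes:
#' cells where the target equals 1 contribute `(1 - p)^alpha * log(p)`, all
#' other cells contribute `(1 - O)^beta * p^alpha * log(1 - p)` (`O` is the
#' Gaussian target, which down-weights negatives near a peak). The negated
#' sum is divided by the number of keypoints `K`; with no keypoints and an
#' all-background target the background term is normalised by 1.
#'
#' @param pred predicted heatmap (array, values in `(0, 1)`; clamped to
#'   `[1e-7, 1 - 1e-7]` before logs).
#' @param target target heatmap of the same shape (1 exactly at keypoint
#'   cells).
#' @param n_keypoints number of encoded keypoints `K`; defaults to the
#'   number of cells where `target == 1`.
#' @param alpha,beta focal exponents (defaults 2 and 4).
#' @param grad if `TRUE`, also return the analytic gradient wrt `pred`.
#' @return The loss (scalar), or `list(loss, grad)` when `grad = TRUE`.
#' @export
heatmap_loss <- function(pred, target, n_keypoints = NULL, alpha = 2, beta = 4,
                         grad = FALSE) {
  stopifnot(length(pred) == length(target))
  pos <- target == 1
  if (is.null(n_keypoints)) n_keypoints <- sum(pos)
  if (n_keypoints == 0 && any(pos))
    stop("n_keypoints is 0 but the target contains foreground cells")
  K <- max(1, n_keypoints)
  eps <- 1e-7
  p <- pmin(1 - eps, pmax(eps, pred))
  loss_terms <- ifelse(pos,
                       (1 - p)^alpha * log(p),
                       (1 - target)^beta * p^alpha * log(1 - p))
  loss <- -sum(loss_terms) / K
  if (!grad) return(loss)
  g <- ifelse(pos,
              -alpha * (1 - p)^(alpha - 1) * log(p) + (1 - p)^alpha / p,
              (1 - target)^beta * (alpha * p^(alpha - 1) * log(1 - p) - p^alpha / (1 - p)))
  g <- -g / K
  dim(g) <- dim(pred)
  list(loss = loss, grad = g)
}

#' L1 radius loss
#'
#' Mean absolute error between predicted and target radii at keypoint cells
#' (both in output-grid units).
#'
#' @param pred,target equal-length numeric vectors of radii at the `K`
#'   keypoint cells.
#' @param grad if `TRUE`, also return the (sub)gradient wrt `pred`.
#' @return The loss, or `list(loss, grad)`.
#' @export
radius_loss <- function(pred, target, grad = FALSE) {
  stopifnot(length(pred) == length(target))
  K <- length(pred)
  if (K == 0) return(if (grad) list(loss = 0, grad = numeric(0)) else 0)
  loss <- sum(abs(pred - target)) / K
  if (!grad) return(loss)
  list(loss = loss, grad = sign(pred - target) / K)
}

#' L1 offset loss
#'
#' For each keypoint with true centre `d` the regression target is the
#' fractional part `d / R - floor(d / R)` lost by down-sampling. The loss is
#' the mean (over keypoints) of the summed absolute x- and y-errors.
#'
#' @param pred `K x 2` matrix of predicted offsets (x then y) at keypoint cells.
#' @param centers `K x 2` matrix of true centres in input pixels.
#' @param stride the down-sampling factor `R`.
#' @param grad if `TRUE`, also return the (sub)gradient wrt `pred`.
#' @return The loss, or `list(loss, grad)`.
#' @export
offset_loss <- function(pred, centers, stride, grad = FALSE) {
  pred <- rbind(pred); centers <- rbind(centers)
  stopifnot(ncol(pred) == 2, all(dim(pred) == dim(centers)))
  K <- nrow(pred)
  if (K == 0) return(if (grad) list(loss = 0, grad = pred) else 0)
  tgt <- centers / stride - floor(centers / stride)
  loss <- sum(abs(pred - tgt)) / K
  if (!grad) return(loss)
  list(loss = loss, grad = sign(pred - tgt) / K)
}

#' Weighted total detection loss
#'
#' `Lh + lambda_r * Lr + lambda_o * Lo`.
#'
#' @param lh,lr,lo heatmap, radius and offset loss values.
#' @param w a [loss_weights()].
#' @return The combined scalar loss.
#' @export
total_loss <- function(lh, lr, lo, w = loss_weights()) {
  stopifnot(is.finite(lh), is.finite(lr), is.finite(lo))
  lh + w$lambda_r * lr + w$lambda_o * lo
}

# Full multi-task loss on one image's output maps vs encoded targets.
# Returns component losses, the total, and gradients wrt the three maps
# (same shapes as the predictions). Used by the training loop.
detection_loss <- function(pred_heatmap, pred_offset, pred_radius, targets,
                           w = loss_weights()) {
  mask_idx <- which(targets$mask == 1)
  K <- length(mask_idx)
  hl <- heatmap_loss(pred_heatmap, targets$heatmap, n_keypoints = targets$n_keypoints,
                     alpha = w$alpha, beta = w$beta, grad = TRUE)
  Ho <- dim(targets$mask)[1]; Wo <- dim(targets$mask)[2]
  if (length(dim(pred_radius)) == 3) pred_radius <- pred_radius[, , 1]

  gr <- array(0, c(Ho, Wo))
  go <- array(0, c(Ho, Wo, 2))
  if (K > 0) {
    rl <- radius_loss(pred_radius[mask_idx], targets$radius[mask_idx], grad = TRUE)
    gr[mask_idx] <- rl$grad
    po <- cbind(pred_offset[, , 1][mask_idx], pred_offset[, , 2][mask_idx])
    to <- cbind(targets$offset[, , 1][mask_idx], targets$offset[, , 2][mask_idx])
    odiff <- po - to
    lo <- sum(abs(odiff)) / K
    go[, , 1][mask_idx] <- sign(odiff[, 1]) / K
    go[, , 2][mask_idx] <- sign(odiff[, 2]) / K
    lr <- rl$loss
  } else {
    lr <- 0; lo <- 0
  }
  list(heatmap = hl$loss, radius = lr, offset = lo,
       total = total_loss(hl$loss, lr, lo, w),
       grad_heatmap = hl$grad,
       grad_radius = w$lambda_r * gr,
       grad_offset = w$lambda_o * go)
}
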
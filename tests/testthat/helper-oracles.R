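# Independent reference implementations used as oracles. These deliberately
# avoid the package's analytic code paths.

# Rasterisation oracle for disk intersection: overlay the intersection of
# the two circles' bounding boxes (which contains the lens) with an n x n
# sub-pixel grid and count the cells whose centres fall inside both disks
# (computed row by row with exact column-index interval counts, which
# enumerates exactly the same cells as a full 2-D scan).
raster_intersection_area <- function(a, b, n = 4096) {
  x0 <- max(a$cx - a$r, b$cx - b$r); x1 <- min(a$cx + a$r, b$cx + b$r)
  y0 <- max(a$cy - a$r, b$cy - b$r); y1 <- min(a$cy + a$r, b$cy + b$r)
  hx <- (x1 - x0) / n; hy <- (y1 - y0) / n
  if (hx <= 0 || hy <= 0) return(0)
  yc <- y0 + (seq_len(n) - 0.5) * hy
  # columns j (1-based) have centres x0 + (j - 0.5) * hx
  count_cols <- function(lo, hi) {
    j_lo <- ceiling((lo - x0) / hx + 0.5)
    j_hi <- floor((hi - x0) / hx + 0.5)
    pmax(0, pmin(j_hi, n) - pmax(j_lo, 1) + 1)
  }
  da <- a$r^2 - (yc - a$cy)^2
  db <- b$r^2 - (yc - b$cy)^2
  ok <- da > 0 & db > 0
  if (!any(ok)) return(0)
  wa <- sqrt(da[ok]); wb <- sqrt(db[ok])
  lo <- pmax(a$cx - wa, b$cx - wb)
  hi <- pmin(a$cx + wa, b$cx + wb)
  good <- hi > lo
  sum(count_cols(lo[good], hi[good])) * hx * hy
}

# Exhaustive 8-neighbourhood peak scan.
brute_peaks <- function(m) {
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m) &&
          m[i, j] < m[ii, jj]) out[i, j] <- FALSE
    }
  }
  out
}

# O(n^2) greedy NMS reference.
brute_nms <- function(dets, thresh) {
  ord <- order(-dets$score, dets$cy, dets$cx, dets$r)
  dets <- dets[ord, , drop = FALSE]
  kept <- list()
  for (i in seq_len(nrow(dets))) {
    ok <- TRUE
    for (k in kept) {
      if (k$class_id != dets$class_id[i]) next
      if (circle_iou(dets[i, , drop = FALSE], k) >= thresh) { ok <- FALSE; break }
    }
    if (ok) kept[[length(kept) + 1]] <- dets[i, , drop = FALSE]
  }
  out <- do.call(rbind, kept)
  rownames(out) <- NULL
  out
}

# Greedy-by-score matching reference returning TP flags in score order.
brute_match_flags <- function(dets, gts, thresh) {
  ord <- order(-dets$score, dets$cy, dets$cx, dets$r)
  dets <- dets[ord, , drop = FALSE]
  used <- rep(FALSE, nrow(gts))
  flags <- logical(nrow(dets))
  for (i in seq_len(nrow(dets))) {
    best <- 0; bj <- 0
    for (j in seq_len(nrow(gts))) {
      if (used[j] || gts$class_id[j] != dets$class_id[i]) next
      v <- circle_iou(dets[i, , drop = FALSE], gts[j, , drop = FALSE])
      if (v > best) { best <- v; bj <- j }
    }
    if (bj > 0 && best >= thresh) { flags[i] <- TRUE; used[bj] <- TRUE }
  }
  flags
}

# PR-curve AP computed directly from TP flags (all-point interpolation).
brute_ap <- function(flags, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (length(flags) == 0) return(0)
  tp <- cumsum(flags); fp <- cumsum(!flags)
  rec <- tp / n_gt; prec <- tp / (tp + fp)
  ap <- 0; prev_r <- 0
  for (i in seq_along(rec)) {
    p_at <- max(prec[i:length(prec)])
    ap <- ap + (rec[i] - prev_r) * p_at
    prev_r <- rec[i]
  }
  ap
}

# Central finite differences of a scalar function of an array.
num_grad <- function(f, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

# Direct nested-loop 2-D cross-correlation (conv layer reference).
naive_conv <- function(x, w, b, stride, pad) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]; N <- dim(x)[4]
  k <- dim(w)[1]; Co <- dim(w)[4]
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  y <- array(0, c(Ho, Wo, Co, N))
  for (n in 1:N) for (co in 1:Co) for (oh in 1:Ho) for (ow in 1:Wo) {
    acc <- b[co]
    for (ci in 1:C) for (i in 1:k) for (j in 1:k) {
      h <- (oh - 1) * stride - pad + (i - 1)
      ww <- (ow - 1) * stride - pad + (j - 1)
      if (h >= 0 && h < H && ww >= 0 && ww < W)
        acc <- acc + x[h + 1, ww + 1, ci, n] * w[i, j, ci, co]
    }
    y[oh, ow, co, n] <- acc
  }
  y
}

# Random detection/ground-truth sets on a small canvas.
random_circles <- function(n, with_score = FALSE, size = 100) {
  d <- data.frame(cx = runif(n, 10, size - 10), cy = runif(n, 10, size - 10),
                  r = runif(n, 3, 12), class_id = sample(1:2, n, replace = TRUE))
  if (with_score) d$score <- round(runif(n), 3)
  d
}
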
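test_that("gaussian_value follows the kernel closed form", {
  expect_equal(gaussian_value(0, 2), 1)
  expect_equal(gaussian_value(2 * 1.5^2, 1.5), exp(-1))
  expect_lt(gaussian_value(1e6, 1), 1e-10)
  expect_error(gaussian_value(1, 0), "sigma")
})

test_that("encoding places peaks, offsets and radii by the stride convention", {
  cfg <- codec_config(stride = 4)
  # exactly divisible centre: cell (u=2, v=2), zero offset, radius r/R
  tm <- encode_targets(circles(8, 8, 4), c(32, 32), cfg)
  expect_equal(tm$heatmap[3, 3, 1], 1)
  expect_equal(tm$offset[3, 3, ], c(0, 0))
  expect_equal(tm$radius[3, 3], 1)
  expect_equal(tm$mask[3, 3], 1)
  expect_equal(sum(tm$mask), 1)
  expect_equal(tm$n_keypoints, 1)
  # fractional centre: (10, 6) / 4 -> cell (2, 1), offsets (0.5, 0.5)
  tm2 <- encode_targets(circles(10, 6, 8), c(32, 32), cfg)
  expect_equal(tm2$offset[2, 3, ], c(0.5, 0.5))
  expect_equal(tm2$radius[2, 3], 2)
  expect_equal(tm2$mask[2, 3], 1)
})

test_that("empty and invalid annotations are handled", {
  cfg <- codec_config()
  tm <- encode_targets(circles(numeric(0), numeric(0), numeric(0)), c(64, 64), cfg)
  expect_equal(max(tm$heatmap), 0)
  expect_equal(tm$n_keypoints, 0)
  expect_error(encode_targets(circles(200, 10, 5), c(64, 64), cfg), "outside")
  expect_warning(encode_targets(circles(c(8, 9), c(8, 9), c(4, 4)), c(64, 64), cfg),
                 "share output cell")
})

test_that("heatmap equals the max of per-annotation Gaussian bumps", {
  cfg <- codec_config(stride = 4)
  anns <- circles(c(12, 48), c(16, 40), c(6, 10))
  tm <- encode_targets(anns, c(64, 64), cfg)
  # direct per-pixel evaluation of the kernel at every cell
  ref <- matrix(0, 16, 16)
  for (k in 1:2) {
    u <- floor(anns$cx[k] / 4); v <- floor(anns$cy[k] / 4)
    sig <- max(1, (anns$r[k] / 4) / 3)
    for (i in 1:16) for (j in 1:16) {
      val <- gaussian_value((j - 1 - u)^2 + (i - 1 - v)^2, sig)
      ref[i, j] <- max(ref[i, j], val)
    }
  }
  expect_equal(tm$heatmap[, , 1], ref)
  expect_equal(max(tm$heatmap), 1)
  expect_equal(sum(tm$mask), 2)
})

test_that("peak extraction matches the exhaustive neighbourhood scan", {
  cfg <- codec_config(top_h = 200, score_threshold = 0)
  m <- matrix(0, 5, 5); m[3, 4] <- 1
  pk <- extract_peaks(m, codec_config(score_threshold = 0.1))
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$u, pk$v), c(3, 2))   # 0-based (column, row)
  expect_equal(nrow(extract_peaks(matrix(0, 5, 5),
                                  codec_config(score_threshold = 0.1))), 0)
  set.seed(41)
  for (i in 1:100) {
    m <- matrix(runif(15 * 13), 15, 13)
    pk <- extract_peaks(m, cfg)
    ref <- which(brute_peaks(m), arr.ind = TRUE)
    expect_equal(nrow(pk), nrow(ref))
    expect_setequal(paste(pk$v, pk$u), paste(ref[, 1] - 1, ref[, 2] - 1))
    expect_true(all(diff(pk$score) <= 0))
  }
})

test_that("top_h truncation and score threshold apply after ranking", {
  m <- matrix(0, 8, 8)
  m[cbind(c(2, 5, 7), c(2, 5, 7))] <- c(0.9, 0.6, 0.2)
  pk <- extract_peaks(m, codec_config(top_h = 2, score_threshold = 0.1))
  expect_equal(pk$score, c(0.9, 0.6))
  pk2 <- extract_peaks(m, codec_config(top_h = 100, score_threshold = 0.5))
  expect_equal(nrow(pk2), 2)
})

test_that("decode inverts encode exactly for distinct cells", {
  cfg <- codec_config(score_threshold = 0.3)
  set.seed(51)
  for (i in 1:20) {
    n <- sample(1:5, 1)
    anns <- data.frame(cx = runif(n, 10, 117), cy = runif(n, 10, 117),
                       r = runif(n, 4, 14), class_id = 1L)
    cells <- paste(floor(anns$cx / 4), floor(anns$cy / 4))
    if (anyDuplicated(cells)) next
    tm <- encode_targets(anns, c(128, 128), cfg)
    dets <- decode_detections(tm$heatmap, tm$offset, tm$radius, cfg, nms = FALSE)
    dets <- dets[dets$score == 1, , drop = FALSE]
    expect_equal(nrow(dets), n)
    ord_d <- order(dets$cx, dets$cy); ord_a <- order(anns$cx, anns$cy)
    expect_equal(dets$cx[ord_d], anns$cx[ord_a], tolerance = 1e-9)
    expect_equal(dets$cy[ord_d], anns$cy[ord_a], tolerance = 1e-9)
    expect_equal(dets$r[ord_d], anns$r[ord_a], tolerance = 1e-9)
  }
})

test_that("decoding degenerate maps is safe", {
  cfg <- codec_config()
  hm <- array(0, c(8, 8, 1)); off <- array(0, c(8, 8, 2)); rad <- matrix(0, 8, 8)
  expect_equal(nrow(decode_detections(hm, off, rad, cfg)), 0)
  # single peak inverse of the worked encoding example
  hm[2, 3, 1] <- 0.8
  off[2, 3, 1] <- 0.5; off[2, 3, 2] <- 0.5
  rad[2, 3] <- 2
  d <- decode_detections(hm, off, rad, cfg)
  expect_equal(c(d$cx, d$cy, d$r, d$score), c(10, 6, 8, 0.8))
  # negative radii clamp to zero
  rad[2, 3] <- -1
  expect_equal(decode_detections(hm, off, rad, cfg)$r, 0)
})

test_that("decoded scores are non-increasing", {
  set.seed(61)
  hm <- array(runif(16 * 16), c(16, 16, 1))
  off <- array(runif(16 * 16 * 2), c(16, 16, 2))
  rad <- matrix(runif(16 * 16, 0, 3), 16, 16)
  d <- decode_detections(hm, off, rad, codec_config(score_threshold = 0), nms = FALSE)
  expect_true(all(diff(d$score) <= 0))
  expect_lte(nrow(d), codec_config()$top_h)
})
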
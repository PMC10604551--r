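test_that("greedy matching pairs perfect detections and flags FPs", {
  gts <- circles(c(20, 60), c(20, 60), c(8, 10), class_id = 1)
  perfect <- cbind(gts, score = 1)
  m <- match_detections(perfect, gts)
  expect_true(all(!is.na(m$gt)))
  expect_equal(sort(m$gt), 1:2)
  expect_equal(m$iou, c(1, 1))
  none <- match_detections(perfect, gts[0, ])
  expect_true(all(is.na(none$gt)))
  # class mismatch prevents matching
  wrong <- perfect; wrong$class_id <- 2
  expect_true(all(is.na(match_detections(wrong, gts)$gt)))
})

test_that("matching agrees with the brute-force greedy oracle", {
  set.seed(131)
  for (i in 1:25) {
    dets <- random_circles(sample(1:10, 1), with_score = TRUE)
    gts <- random_circles(sample(1:10, 1))
    m <- match_detections(dets, gts, 0.3)
    expect_equal(!is.na(m$gt), brute_match_flags(dets, gts, 0.3))
  }
})

test_that("AP reproduces hand-enumerated and degenerate cases", {
  gts <- cbind(circles(c(20, 60), c(20, 60), c(8, 10), class_id = 1),
               file = "a.png")
  perfect <- cbind(gts[, c("cx", "cy", "r", "class_id")], score = 1, file = "a.png")
  expect_equal(average_precision(perfect, gts), 1)
  expect_equal(average_precision(perfect[0, ], gts), 0)
  expect_warning(ap <- average_precision(perfect, gts[0, ]), "undefined")
  expect_true(is.na(ap))
  # 2 GT; one TP at score .9 then one FP at .8 -> PR (1, .5), (.5, .5) -> 0.5
  dets <- data.frame(file = "a.png", cx = c(20, 90), cy = c(20, 90),
                     r = c(8, 5), class_id = 1L, score = c(0.9, 0.8))
  expect_equal(average_precision(dets, gts), 0.5)
  # 11-point variant: recall levels 0..0.5 see precision 1, the rest 0
  expect_equal(average_precision(dets, gts, interpolation = "11point"), 6 / 11)
})

test_that("AP equals the brute-force PR enumeration on random sets", {
  set.seed(141)
  for (i in 1:25) {
    nd <- sample(0:10, 1); ng <- sample(1:10, 1)
    dets <- random_circles(nd, with_score = TRUE)
    dets$file <- rep("a.png", nd); dets$class_id <- rep(1L, nd)
    gts <- random_circles(ng)
    gts$file <- rep("a.png", ng); gts$class_id <- rep(1L, ng)
    flags <- brute_match_flags(dets, gts, 0.5)
    expect_equal(average_precision(dets, gts, 0.5), brute_ap(flags, ng))
  }
})

test_that("AP is invariant to positive score rescaling and FP monotone", {
  set.seed(151)
  dets <- cbind(random_circles(8, with_score = TRUE), file = "a.png")
  dets$class_id <- 1L
  gts <- cbind(random_circles(6), file = "a.png")
  gts$class_id <- 1L
  ap <- average_precision(dets, gts)
  scaled <- dets; scaled$score <- scaled$score * 0.37
  expect_equal(average_precision(scaled, gts), ap)
  worst <- rbind(dets, data.frame(file = "a.png", cx = 1, cy = 1, r = 1,
                                  class_id = 1L, score = min(dets$score) / 2))
  expect_lte(average_precision(worst, gts), ap)
})

test_that("mean AP averages defined classes only", {
  expect_equal(mean_ap(0.7), 0.7)
  expect_equal(mean_ap(c(1, 0.5)), 0.75)
  expect_warning(m <- mean_ap(c(0.6, NA)), "undefined")
  expect_equal(m, 0.6)
  expect_error(suppressWarnings(mean_ap(NA_real_)), "no class")
})

test_that("image classification rule thresholds the best detection", {
  expect_equal(classify_image(data.frame(score = numeric(0))), "negative")
  expect_equal(classify_image(data.frame(score = 0.9), tau = 0.5), "positive")
  expect_equal(classify_image(data.frame(score = 0.4), tau = 0.5), "negative")
})

test_that("classification metrics follow their defining ratios", {
  m <- classification_metrics(tp = 3, tn = 2, fp = 1, fn = 4)
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 3 / 7)
  # harmonic mean: precision 1 and recall 0 give F1 = 0, not 0.5
  m2 <- classification_metrics(tp = 0, tn = 5, fp = 0, fn = 5)
  expect_true(is.na(m2$precision))
  expect_equal(m2$recall, 0)
  m3 <- suppressWarnings(classification_metrics(tp = 0, tn = 0, fp = 1, fn = 1))
  expect_equal(m3$precision, 0)
  expect_equal(m3$recall, 0)
  expect_equal(m3$f1, 0)
  expect_warning(classification_metrics(0, 10, 0, 0), "undefined")
})

test_that("the published precision/recall pair yields the published F1", {
  p <- 0.968; r <- 0.961
  f1 <- classification_metrics(tp = 961, tn = 0, fp = round(961 / p - 961),
                               fn = round(961 / r - 961))$f1
  expect_equal(2 * p * r / (p + r), 0.9645, tolerance = 5e-5)
  expect_equal(f1, 0.9645, tolerance = 5e-4)
})

test_that("the full report combines localisation and classification", {
  gts <- data.frame(file = rep(c("a", "b"), each = 2),
                    cx = c(20, 60, 30, 70), cy = c(20, 60, 30, 70),
                    r = c(8, 9, 10, 7), class_id = 1L)
  preds <- cbind(gts[, c("file", "cx", "cy", "r", "class_id")], score = 1)
  rep <- evaluate_predictions(preds, gts, images = c("a", "b", "c"))
  expect_equal(rep$map, 1)
  expect_equal(rep$mean_matched_iou, 1)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$tn, 1)                 # image "c" has neither GT nor dets
  # empty predictions: zero recall, mAP 0
  rep0 <- suppressWarnings(evaluate_predictions(preds[0, ], gts,
                                                images = c("a", "b", "c")))
  expect_equal(rep0$map, 0)
  expect_equal(rep0$recall, 0)
  # matched IoU lies above the threshold by construction
  jit <- preds; jit$cx <- jit$cx + 2
  repj <- evaluate_predictions(jit, gts, images = c("a", "b"))
  expect_gte(repj$mean_matched_iou, 0.5)
  expect_lte(repj$mean_matched_iou, 1)
})
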
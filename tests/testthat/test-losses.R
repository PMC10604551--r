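test_that("focal heatmap loss reproduces closed-form spot values", {
  # perfect prediction: zero loss in both branches
  tgt <- matrix(0, 3, 3); tgt[2, 2] <- 1
  pred <- matrix(0, 3, 3); pred[2, 2] <- 1
  expect_equal(heatmap_loss(pred, tgt), 0, tolerance = 1e-6)
  # single foreground cell at 0.5: -(1-0.5)^2 log 0.5
  expect_lt(abs(heatmap_loss(matrix(0.5), matrix(1)) - 0.173287), 1e-6)
  # Gaussian-tail background cell: -(1-0.5)^4 0.5^2 log(1-0.5), K fixed at 1
  expect_lt(abs(heatmap_loss(matrix(0.5), matrix(0.5), n_keypoints = 1) -
                  0.010830), 1e-6)
  expect_error(heatmap_loss(matrix(0.5), matrix(1), n_keypoints = 0), "foreground")
})

test_that("heatmap loss decreases as the peak prediction approaches 1", {
  tgt <- matrix(c(1, 0.2, 0, 0), 2, 2)
  vals <- vapply(seq(0.05, 0.95, 0.1), function(p) {
    pred <- matrix(c(p, 0.1, 0.1, 0.1), 2, 2)
    heatmap_loss(pred, tgt)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("L1 radius and offset losses follow their normalisation", {
  expect_equal(radius_loss(c(3, 7), c(3, 7)), 0)
  expect_equal(radius_loss(3, 5), 2)
  expect_equal(radius_loss(c(3, 7), c(5, 5)), 2)
  expect_equal(radius_loss(numeric(0), numeric(0)), 0)
  # offsets: target for x = 10, R = 4 is 0.5
  expect_equal(offset_loss(cbind(0.3, 0), cbind(10, 8), 4), 0.2)
  expect_equal(offset_loss(cbind(0.5, 0.5), cbind(10, 10), 4), 0)
  # per-keypoint x+y errors (0.1, 0.1) and (0.3, 0.3), K = 2 -> 0.4
  pred <- rbind(c(0.6, 0.6), c(0.8, 0.8))
  ctr <- rbind(c(2, 2), c(2, 2))        # targets (0.5, 0.5) at R = 4
  expect_equal(offset_loss(pred, ctr, 4), 0.4)
})

test_that("total loss is the weighted sum with the published weights", {
  expect_equal(total_loss(1, 2, 0.5), 1.7)
  expect_equal(total_loss(0, 0, 0), 0)
  expect_equal(total_loss(3, 10, 10, loss_weights(lambda_r = 0, lambda_o = 0)), 3)
})

test_that("losses vanish on targets derived from the codec", {
  cfg <- codec_config(stride = 4)
  anns <- circles(c(12, 50.5), c(17, 41), c(6, 9))
  tm <- encode_targets(anns, c(64, 64), cfg)
  pred_heat <- (tm$heatmap == 1) * 1
  mask_idx <- which(tm$mask == 1)
  expect_equal(heatmap_loss(pred_heat, tm$heatmap, tm$n_keypoints), 0,
               tolerance = 1e-6)
  expect_equal(radius_loss(tm$radius[mask_idx], tm$radius[mask_idx]), 0)
  po <- cbind(tm$offset[, , 1][mask_idx], tm$offset[, , 2][mask_idx])
  # order annotations by their linear mask-cell index to pair with `po`
  lin <- (floor(anns$cy / 4) + 1) + floor(anns$cx / 4) * nrow(tm$mask)
  ctr <- cbind(anns$cx, anns$cy)[order(lin), , drop = FALSE]
  expect_equal(offset_loss(po, ctr, 4), 0, tolerance = 1e-12)
})

test_that("analytic loss gradients match finite differences", {
  set.seed(71)
  tgt <- matrix(runif(20), 4, 5)
  tgt[cbind(c(1, 3), c(2, 4))] <- 1
  pred <- matrix(runif(20, 0.05, 0.95), 4, 5)
  hl <- heatmap_loss(pred, tgt, grad = TRUE)
  gnum <- num_grad(function(p) heatmap_loss(p, tgt), pred)
  expect_equal(hl$grad, gnum, tolerance = 1e-4)

  pr <- runif(5, 0, 3); tr <- runif(5, 0, 3)
  rl <- radius_loss(pr, tr, grad = TRUE)
  expect_equal(rl$grad, num_grad(function(p) radius_loss(p, tr), pr),
               tolerance = 1e-4)

  po <- matrix(runif(6), 3, 2); ctr <- matrix(runif(6, 0, 40), 3, 2)
  ol <- offset_loss(po, ctr, 4, grad = TRUE)
  expect_equal(ol$grad, num_grad(function(p) offset_loss(p, ctr, 4), po),
               tolerance = 1e-4)
})

test_that("combined detection loss gradient matches finite differences", {
  set.seed(81)
  cfg <- codec_config(stride = 4)
  tm <- encode_targets(circles(c(9, 22), c(13, 6), c(5, 7)), c(32, 32), cfg)
  ph <- array(runif(8 * 8, 0.1, 0.9), c(8, 8, 1))
  po <- array(runif(8 * 8 * 2), c(8, 8, 2))
  pr <- matrix(runif(8 * 8, 0.1, 3), 8, 8)
  dl <- circlenet:::detection_loss(ph, po, pr, tm)
  f <- function(h, o, r) {
    v <- circlenet:::detection_loss(h, o, r, tm)
    v$total
  }
  expect_equal(dl$grad_heatmap,
               num_grad(function(h) f(h, po, pr), ph), tolerance = 1e-4)
  expect_equal(dl$grad_offset,
               num_grad(function(o) f(ph, o, pr), po), tolerance = 1e-4)
  expect_equal(array(dl$grad_radius, dim(pr)),
               num_grad(function(r) f(ph, po, r), pr), tolerance = 1e-4)
})
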
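test_that("residual block with zero residual weights is the identity", {
  set.seed(101)
  blk <- residual_block(4, 4, stride = 1)
  blk$conv1$params$w[] <- 0; blk$conv1$params$b[] <- 0
  blk$conv2$params$w[] <- 0; blk$conv2$params$b[] <- 0
  x <- array(runif(8 * 8 * 4), c(8, 8, 4))   # non-negative input
  y <- apply_block(blk, x, training = FALSE)
  expect_equal(y, x, tolerance = 1e-12)
})

test_that("residual block shape contract holds for stride 1 and 2", {
  set.seed(102)
  x <- array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  y1 <- apply_block(residual_block(4, 4, stride = 1), x)
  expect_equal(dim(y1), dim(x))
  y2 <- apply_block(residual_block(4, 6, stride = 2), x)
  expect_equal(dim(y2), c(4, 4, 6, 2))
})

test_that("CBAM with saturated gates is the identity and bounds output", {
  set.seed(103)
  blk <- cbam_block(8, reduction = 4, spatial_kernel = 3)
  blk$params$b2[] <- 50     # channel gate -> 1
  blk$params$ws[] <- 0
  blk$params$bs[] <- 50     # spatial gate -> 1
  x <- array(rnorm(6 * 6 * 8), c(6, 6, 8))
  expect_equal(apply_block(blk, x), x, tolerance = 1e-12)
  # generic gates only shrink magnitudes
  blk2 <- cbam_block(8, reduction = 4, spatial_kernel = 3)
  y <- apply_block(blk2, x)
  expect_true(all(abs(y) <= abs(x) + 1e-12))
})

test_that("CBAM equals the manual composition of its two gate stages", {
  set.seed(104)
  blk <- cbam_block(6, reduction = 2, spatial_kernel = 3)
  x <- array(rnorm(5 * 7 * 6 * 1), c(5, 7, 6, 1))
  y <- circlenet:::layer_forward(blk, x)
  # stage 1: channel gate from global average/max descriptors
  P <- 5 * 7
  xm <- x; dim(xm) <- c(P, 6)
  A <- colMeans(xm); M <- apply(xm, 2, max)
  mlp <- function(v) blk$params$w2 %*% pmax(blk$params$w1 %*% v + blk$params$b1, 0) +
    blk$params$b2
  gate_c <- 1 / (1 + exp(-(mlp(A) + mlp(M))))
  y1 <- sweep(xm, 2, as.vector(gate_c), "*")
  # stage 2: spatial gate from channel mean/max maps
  stats <- array(c(rowMeans(y1), apply(y1, 1, max)), c(5, 7, 2, 1))
  zs <- circlenet:::cn_conv2d_forward(stats, blk$params$ws, blk$params$bs, 1L, 1L)
  gate_s <- 1 / (1 + exp(-as.vector(zs)))
  y_ref <- array(y1 * gate_s, c(5, 7, 6, 1))
  expect_equal(y, y_ref, tolerance = 1e-12)
})

test_that("network output shapes follow the stride contract", {
  set.seed(105)
  cfg <- backbone_config(stage_blocks = c(1, 1, 1, 1), base_channels = 8,
                         cbam_reduction = 4)
  net <- build_network(cfg, codec_config(stride = 4), seed = 2)
  out <- network_forward(net, array(runif(64 * 64 * 3), c(64, 64, 3)))
  expect_equal(dim(out$heatmap), c(16, 16, 1, 1))
  expect_equal(dim(out$offset), c(16, 16, 2, 1))
  expect_equal(dim(out$radius), c(16, 16, 1, 1))
  expect_true(all(out$heatmap > 0 & out$heatmap < 1))
  expect_error(network_forward(net, array(0, c(60, 60, 3))), "divisible by 32")
})

test_that("the tiny variant has strictly fewer parameters than the full one", {
  set.seed(106)
  tiny <- build_network(backbone_config(tiny = TRUE), seed = 1)
  full <- build_network(backbone_config(), seed = 1)
  expect_lt(count_parameters(tiny), count_parameters(full))
})

test_that("forward pass is deterministic given fixed weights", {
  set.seed(107)
  net <- build_network(backbone_config(stage_blocks = c(1, 1, 1, 1),
                                       base_channels = 8, cbam_reduction = 4),
                       seed = 3)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  o1 <- network_forward(net, x)
  o2 <- network_forward(net, x)
  expect_identical(o1, o2)
})

test_that("checkpoints restore weights, stats and configs exactly", {
  set.seed(108)
  net <- build_network(backbone_config(stage_blocks = c(1, 1, 1, 1),
                                       base_channels = 8, cbam_reduction = 4),
                       codec_config(stride = 8), seed = 4)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  invisible(network_forward(net, x, training = TRUE))  # populate running stats
  path <- tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  net2 <- load_checkpoint(path)
  expect_equal(net2$codec$stride, 8L)
  expect_equal(network_forward(net2, x), network_forward(net, x))
})

test_that("one optimisation step on one example decreases the total loss", {
  set.seed(109)
  net <- build_network(backbone_config(stage_blocks = c(1, 1, 1, 1),
                                       base_channels = 8, cbam_reduction = 4),
                       seed = 5)
  sc <- generate_scene(scene_spec(seed = 9, size = c(64, 64), n_cells = 2,
                                  radius_range = c(6, 12)))
  tm <- encode_targets(sc$annotations, c(64, 64))
  xb <- array(sc$image, c(64, 64, 3, 1))
  refs <- unlist(lapply(circlenet:::net_modules(net),
                        circlenet:::collect_param_refs), recursive = FALSE)
  opt <- circlenet:::optimizer_init(refs, "adam", lr = 1e-3)
  w <- loss_weights()
  s1 <- circlenet:::train_step(net, opt, xb, list(tm), w)
  s2 <- circlenet:::train_step(net, s1$opt, xb, list(tm), w)
  expect_lt(s2$losses[["total"]], s1$losses[["total"]])
})
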
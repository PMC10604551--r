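make_tile <- function(seed = 7, n = 2, size = c(64, 64))
  generate_scene(scene_spec(seed = seed, size = size, n_cells = n,
                            radius_range = c(6, 10)))

test_that("horizontal flip mirrors coordinates and is an involution", {
  sc <- make_tile()
  a <- augment_hflip(sc$image, sc$annotations)
  expect_equal(a$anns$cx, 63 - sc$annotations$cx)
  expect_equal(a$anns$cy, sc$annotations$cy)
  b <- augment_hflip(a$image, a$anns)
  expect_identical(b$image, sc$image)
  expect_equal(b$anns, sc$annotations)
  # worked example: W = 100, cx = 10 -> 89; the exact centre is a fixed point
  wide <- list(image = array(0, c(10, 100, 3)),
               anns = circles(c(10, 49.5), c(5, 5), c(2, 2)))
  fl <- augment_hflip(wide$image, wide$anns)
  expect_equal(fl$anns$cx, c(89, 49.5))
})

test_that("quarter-turn rotations form a cyclic group of order four", {
  sc <- make_tile(seed = 8)
  r0 <- augment_rotate90(sc$image, sc$annotations, 0)
  expect_identical(r0$image, sc$image)
  cur <- list(image = sc$image, anns = sc$annotations)
  for (q in 1:4) cur <- augment_rotate90(cur$image, cur$anns, 1)
  expect_identical(cur$image, sc$image)
  expect_equal(cur$anns, sc$annotations)
  # k = 1 mapping on a non-square image
  img <- array(runif(4 * 6 * 3), c(4, 6, 3))
  ann <- circles(5, 1, 1)
  r1 <- augment_rotate90(img, ann, 1)
  expect_equal(dim(r1$image), c(6, 4, 3))
  expect_equal(c(r1$anns$cx, r1$anns$cy), c(1, 0))   # (cy, W-1-cx)
  # half turn equals the two flips composed
  r2 <- augment_rotate90(sc$image, sc$annotations, 2)
  ff <- augment_vflip(sc$image, sc$annotations)
  ff <- augment_hflip(ff$image, ff$anns)
  expect_identical(r2$image, ff$image)
  expect_equal(r2$anns$cx, ff$anns$cx)
  expect_equal(r2$anns$cy, ff$anns$cy)
})

test_that("blur preserves annotations, constants and mean intensity", {
  sc <- make_tile(seed = 9)
  b0 <- augment_blur(sc$image, sc$annotations, 0)
  expect_identical(b0$image, sc$image)
  const <- array(0.4, c(32, 32, 3))
  bc <- augment_blur(const, sc$annotations[0, ], 2)
  expect_equal(bc$image, const, tolerance = 1e-6)
  b <- augment_blur(sc$image, sc$annotations, 1.2)
  expect_equal(b$anns, sc$annotations)
  expect_equal(mean(b$image), mean(sc$image), tolerance = 1e-3)
})

test_that("cropping keeps exactly the circles whose centres fall inside", {
  sc <- make_tile(seed = 10, n = 3)
  full <- augment_crop(sc$image, sc$annotations, c(64, 64), origin = c(0, 0))
  expect_identical(full$image, sc$image)
  expect_equal(nrow(full$anns), 3)
  set.seed(11)
  for (i in 1:20) {
    org <- c(sample(0:32, 1), sample(0:32, 1))
    cr <- augment_crop(sc$image, sc$annotations, c(32, 32), origin = org)
    inside <- sc$annotations$cx >= org[2] & sc$annotations$cx <= org[2] + 31 &
      sc$annotations$cy >= org[1] & sc$annotations$cy <= org[1] + 31
    expect_equal(nrow(cr$anns), sum(inside))
    if (any(inside))
      expect_equal(cr$anns$cx, sc$annotations$cx[inside] - org[2])
  }
  expect_error(augment_crop(sc$image, sc$annotations, c(100, 100)), "exceeds")
})

test_that("free-angle rotation moves centres by the same transform", {
  sc <- make_tile(seed = 12, n = 1)
  r <- augment_rotate(sc$image, sc$annotations, 360)
  expect_equal(r$anns$cx, sc$annotations$cx, tolerance = 1e-9)
  r90 <- augment_rotate(sc$image, sc$annotations, 90)
  q <- augment_rotate90(sc$image, sc$annotations, 3)  # y-down: +90deg = 3 CCW turns
  expect_equal(r90$anns$cx, q$anns$cx, tolerance = 1e-6)
  expect_equal(r90$anns$cy, q$anns$cy, tolerance = 1e-6)
  expect_equal(r$anns$r, sc$annotations$r)
})

test_that("flip and quarter-turn targets commute with encoding", {
  cfg <- codec_config(stride = 4)
  # cell-aligned sub-cell fractions (< 1 - 1/R) so the flipped centre lands in
  # the mirrored cell
  anns <- circles(c(8, 25, 42.5), c(12, 30, 50), c(6, 8, 7))
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  tm <- encode_targets(anns, c(64, 64), cfg)
  fl <- augment_hflip(img, anns)
  tf <- encode_targets(fl$anns, c(64, 64), cfg)
  expect_equal(tf$mask, tm$mask[, ncol(tm$mask):1])
  rot <- augment_rotate90(img, anns, 2)
  tr <- encode_targets(rot$anns, c(64, 64), cfg)
  expect_equal(tr$mask, tm$mask[nrow(tm$mask):1, ncol(tm$mask):1])
  expect_equal(sort(tr$radius[tr$mask == 1]), sort(tm$radius[tm$mask == 1]))
  # decode-level commutation is exact for arbitrary centres
  sc <- make_tile(seed = 13, n = 2)
  aug <- augment_rotate90(sc$image, sc$annotations, 1)
  ta <- encode_targets(aug$anns, c(64, 64), cfg)
  dets <- decode_detections(ta$heatmap, ta$offset, ta$radius, cfg, nms = FALSE)
  dets <- dets[dets$score == 1, , drop = FALSE]
  o1 <- order(dets$cx); o2 <- order(aug$anns$cx)
  expect_equal(dets$cx[o1], aug$anns$cx[o2], tolerance = 1e-9)
  expect_equal(dets$cy[o1], aug$anns$cy[o2], tolerance = 1e-9)
})

test_that("dataset augmentation is seeded, counted and split-preserving", {
  src <- file.path(tempdir(), "aug_src")
  unlink(src, recursive = TRUE)
  tpl <- scene_spec(size = c(64, 64), radius_range = c(6, 10), n_distractors = 1)
  generate_dataset(src, 4, 2, template = tpl, seed = 3)
  cfg <- augment_config(ops = c("hflip", "rotate90"), multiplier = 5, seed = 2)
  o1 <- file.path(tempdir(), "aug_o1"); o2 <- file.path(tempdir(), "aug_o2")
  unlink(c(o1, o2), recursive = TRUE)
  m1 <- augment_dataset(src, cfg, o1)
  m2 <- augment_dataset(src, cfg, o2)
  expect_equal(nrow(m1), 30)              # 6 sources x multiplier 5
  expect_identical(readLines(file.path(o1, "manifest.csv")),
                   readLines(file.path(o2, "manifest.csv")))
  expect_identical(readLines(file.path(o1, "annotations.csv")),
                   readLines(file.path(o2, "annotations.csv")))
  src_man <- read_manifest(file.path(src, "manifest.csv"))
  expect_equal(m1$split, rep(src_man$split, each = 5))
  # annotated copies keep their circle count (flips and quarter turns are lossless)
  expect_equal(m1$n_cells, rep(src_man$n_cells, each = 5))
})
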
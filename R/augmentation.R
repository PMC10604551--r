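# Joint image + circle-annotation augmentation. Geometric ops are exact
# pixel-grid bijections (flip, quarter-turn rotation) or window extraction
# (crop); photometric/resampling ops (blur, free-angle rotation) leave radii
# unchanged. Circle coordinates are 0-based with pixel centres at integers,
# so a horizontal flip maps cx to (W - 1) - cx.

#' Flip an image and its circle annotations
#'
#' @param image array `H x W x 3`.
#' @param anns annotation data frame (`cx`, `cy`, `r`, ...).
#' @return List `(image, anns)` with the transform applied to both.
#' @export
augment_hflip <- function(image, anns) {
  W <- dim(image)[2]
  if (nrow(anns)) anns$cx <- (W - 1) - anns$cx
  list(image = image[, W:1, , drop = FALSE], anns = anns)
}

#' @rdname augment_hflip
#' @export
augment_vflip <- function(image, anns) {
  H <- dim(image)[1]
  if (nrow(anns)) anns$cy <- (H - 1) - anns$cy
  list(image = image[H:1, , , drop = FALSE], anns = anns)
}

#' Lossless quarter-turn rotation
#'
#' Rotates image and annotations counter-clockwise by `k` quarter turns;
#' `k = 1` maps `(cx, cy)` to `(cy, W - 1 - cx)` and swaps the image
#' dimensions. Radii are unchanged.
#'
#' @param image array `H x W x 3`.
#' @param anns annotation data frame.
#' @param k integer in 0..3.
#' @return List `(image, anns)`.
#' @export
augment_rotate90 <- function(image, anns, k = 1L) {
  stopifnot(k %in% 0:3)
  for (q in seq_len(k %% 4)) {
    W <- dim(image)[2]
    rot <- function(m) t(m)[W:1, , drop = FALSE]
    image <- array(c(rot(image[, , 1]), rot(image[, , 2]), rot(image[, , 3])),
                   c(W, dim(image)[1], 3))
    if (nrow(anns)) {
      new_cx <- anns$cy
      anns$cy <- (W - 1) - anns$cx
      anns$cx <- new_cx
    }
  }
  list(image = image, anns = anns)
}

#' Isotropic Gaussian blur (annotations unchanged)
#'
#' @param image array `H x W x 3`.
#' @param anns annotation data frame, returned untouched.
#' @param sigma blur sd in pixels; 0 is the identity.
#' @return List `(image, anns)`.
#' @export
augment_blur <- function(image, anns, sigma) {
  stopifnot(sigma >= 0)
  if (sigma > 0)
    for (ch in 1:3) image[, , ch] <- EBImage::gblur(image[, , ch], sigma)
  list(image = image, anns = anns)
}

#' Random window crop
#'
#' Extracts an `out_size` window; annotations whose centres fall inside the
#' window are shifted to window coordinates, the rest are dropped. Radii are
#' not clipped.
#'
#' @param image array `H x W x 3`.
#' @param anns annotation data frame.
#' @param out_size `c(h, w)` of the window, at most the image size.
#' @param origin optional 0-based `c(oy, ox)` window origin; sampled
#'   uniformly from the current RNG state when `NULL`.
#' @return List `(image, anns, origin)`.
#' @export
augment_crop <- function(image, anns, out_size, origin = NULL) {
  H <- dim(image)[1]; W <- dim(image)[2]
  h <- out_size[1]; w <- out_size[2]
  if (h > H || w > W) stop("crop size exceeds image size")
  if (is.null(origin))
    origin <- c(sample.int(H - h + 1, 1) - 1L, sample.int(W - w + 1, 1) - 1L)
  oy <- origin[1]; ox <- origin[2]
  image <- image[(oy + 1):(oy + h), (ox + 1):(ox + w), , drop = FALSE]
  if (nrow(anns)) {
    keep <- anns$cx >= ox & anns$cx <= ox + w - 1 &
      anns$cy >= oy & anns$cy <= oy + h - 1
    anns <- anns[keep, , drop = FALSE]
    anns$cx <- anns$cx - ox
    anns$cy <- anns$cy - oy
    rownames(anns) <- NULL
  }
  list(image = image, anns = anns, origin = origin)
}

#' Free-angle rotation with bilinear resampling
#'
#' Rotates counter-clockwise by `angle` degrees about the image centre with
#' a reflective border; annotation centres rotate by the same transform and
#' radii are unchanged. Unlike the quarter-turn ops this resamples the
#' image, so it is approximate at the pixel level.
#'
#' @param image array `H x W x 3`.
#' @param anns annotation data frame.
#' @param angle rotation in degrees.
#' @return List `(image, anns)`.
#' @export
augment_rotate <- function(image, anns, angle) {
  H <- dim(image)[1]; W <- dim(image)[2]
  th <- angle * pi / 180
  c0x <- (W - 1) / 2; c0y <- (H - 1) / 2
  gx <- matrix(rep(0:(W - 1), each = H), H, W)
  gy <- matrix(rep(0:(H - 1), W), H, W)
  sx <- cos(th) * (gx - c0x) + sin(th) * (gy - c0y) + c0x
  sy <- -sin(th) * (gx - c0x) + cos(th) * (gy - c0y) + c0y
  reflect <- function(v, n) {
    v <- abs(v)
    p <- 2 * (n - 1)
    v <- v %% p
    ifelse(v > n - 1, p - v, v)
  }
  sx <- reflect(sx, W); sy <- reflect(sy, H)
  x0 <- pmin(floor(sx), W - 2); y0 <- pmin(floor(sy), H - 2)
  fx <- sx - x0; fy <- sy - y0
  iy <- as.vector(y0) + 1; ix <- as.vector(x0) + 1
  out <- image
  for (ch in 1:3) {
    m <- image[, , ch]
    i00 <- m[cbind(iy, ix)]; i01 <- m[cbind(iy, ix + 1)]
    i10 <- m[cbind(iy + 1, ix)]; i11 <- m[cbind(iy + 1, ix + 1)]
    out[, , ch] <- (1 - fy) * ((1 - fx) * i00 + fx * i01) +
      fy * ((1 - fx) * i10 + fx * i11)
  }
  if (nrow(anns)) {
    cx <- anns$cx; cy <- anns$cy
    anns$cx <- cos(th) * (cx - c0x) - sin(th) * (cy - c0y) + c0x
    anns$cy <- sin(th) * (cx - c0x) + cos(th) * (cy - c0y) + c0y
  }
  list(image = out, anns = anns)
}

#' Augmentation configuration
#'
#' @param ops ordered character vector drawn from `hflip`, `vflip`,
#'   `rotate90`, `rotate_any`, `gaussian_blur`, `random_crop`.
#' @param multiplier augmented copies per source image (default 1; 77
#'   reproduces a 455 -> ~35,000 image expansion).
#' @param seed RNG seed for per-copy op sampling.
#' @param p application probability for the optional ops `hflip`, `vflip`
#'   and `gaussian_blur` (default 0.5).
#' @param blur_range uniform range for the blur sd.
#' @param angle_range uniform range (degrees) for `rotate_any`.
#' @param crop_size `c(h, w)` for `random_crop` (`NULL` disables cropping).
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(ops = c("hflip", "vflip", "rotate90"),
                           multiplier = 1L, seed = 1L, p = 0.5,
                           blur_range = c(0.5, 1.5), angle_range = c(-30, 30),
                           crop_size = NULL) {
  known <- c("hflip", "vflip", "rotate90", "rotate_any", "gaussian_blur",
             "random_crop")
  if (!all(ops %in% known))
    stop("unknown ops: ", paste(setdiff(ops, known), collapse = ", "))
  stopifnot(multiplier >= 1)
  structure(list(ops = ops, multiplier = as.integer(multiplier),
                 seed = as.integer(seed), p = p, blur_range = blur_range,
                 angle_range = angle_range, crop_size = crop_size),
            class = "augment_config")
}

apply_random_ops <- function(image, anns, cfg) {
  applied <- character(0)
  for (op in cfg$ops) {
    res <- switch(op,
      hflip = if (runif(1) < cfg$p) augment_hflip(image, anns),
      vflip = if (runif(1) < cfg$p) augment_vflip(image, anns),
      rotate90 = {
        k <- sample(0:3, 1)
        applied <- c(applied, paste0("rot", 90 * k))
        augment_rotate90(image, anns, k)
      },
      rotate_any = {
        a <- runif(1, cfg$angle_range[1], cfg$angle_range[2])
        applied <- c(applied, sprintf("rotany%.1f", a))
        augment_rotate(image, anns, a)
      },
      gaussian_blur = if (runif(1) < cfg$p) {
        s <- runif(1, cfg$blur_range[1], cfg$blur_range[2])
        applied <- c(applied, sprintf("blur%.2f", s))
        augment_blur(image, anns, s)
      },
      random_crop = if (!is.null(cfg$crop_size)) {
        applied <- c(applied, "crop")
        augment_crop(image, anns, cfg$crop_size)
      })
    if (!is.null(res)) {
      image <- res$image; anns <- res$anns
      if (op %in% c("hflip", "vflip")) applied <- c(applied, op)
    }
  }
  list(image = image, anns = anns, ops = paste(applied, collapse = "+"))
}

#' Materialise an augmented dataset
#'
#' Writes `multiplier` augmented copies of every image in a dataset
#' directory, sampling the configured ops per copy from the seeded RNG.
#' Copies inherit their source image's split; image-level labels and cell
#' counts are recomputed from the surviving annotations.
#'
#' @param data_dir source dataset (see [generate_dataset()]).
#' @param cfg an [augment_config()].
#' @param out_dir output dataset directory.
#' @param overwrite allow writing into a non-empty directory.
#' @return The augmented manifest data frame.
#' @export
augment_dataset <- function(data_dir, cfg, out_dir, overwrite = FALSE) {
  man <- read_manifest(file.path(data_dir, "manifest.csv"))
  anns <- read_annotations_csv(file.path(data_dir, "annotations.csv"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("output directory ", out_dir, " is not empty (use overwrite = TRUE)")
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)

  set.seed(cfg$seed)
  out_man <- list(); out_anns <- list(); idx <- 0
  for (i in seq_len(nrow(man))) {
    img <- load_image_png(file.path(data_dir, man$file[i]))
    a <- anns[anns$file == man$file[i], , drop = FALSE]
    for (m in seq_len(cfg$multiplier)) {
      idx <- idx + 1
      res <- apply_random_ops(img, a, cfg)
      file <- sprintf("images/aug_%05d.png", idx)
      save_image_png(res$image, file.path(out_dir, file))
      if (nrow(res$anns)) {
        aa <- res$anns; aa$file <- file
        out_anns[[length(out_anns) + 1]] <-
          aa[, c("file", setdiff(names(aa), "file")), drop = FALSE]
      }
      out_man[[idx]] <- data.frame(
        file = file, label = if (nrow(res$anns)) "positive" else "negative",
        n_cells = nrow(res$anns), seed = cfg$seed,
        split = if ("split" %in% names(man)) man$split[i] else NA_character_,
        source = man$file[i], ops = res$ops)
    }
  }
  out_man <- do.call(rbind, out_man)
  out_anns <- if (length(out_anns)) do.call(rbind, out_anns) else
    data.frame(file = character(0), cx = numeric(0), cy = numeric(0),
               r = numeric(0), class_id = integer(0))
  write_annotations_csv(out_anns, file.path(out_dir, "annotations.csv"))
  write_manifest(out_man, file.path(out_dir, "manifest.csv"))
  out_man
}
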
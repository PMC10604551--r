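#' Synthetic scene specification
#'
#' Seeded parameters for one synthetic histology-like tile. Tiles emulate
#' the appearance that matters to a circle detector — ring-shaped cells of
#' varying size and colour on a stained background, plus distractor blobs,
#' noise and blur — while keeping ground truth exact. Rendering is
#' deliberately schematic (flat-shaded disks with a crescent rim nucleus,
#' the signet morphology), not histologically realistic.
#'
#' @param seed integer RNG seed for the scene.
#' @param size `c(H, W)`, both divisible by 32 (default 128 x 128).
#' @param n_cells number of annotated cells (default 3).
#' @param radius_range `c(r_min, r_max)` in pixels (default `c(8, 16)`).
#' @param palette named list of RGB triplets in `[0, 1]`: `background`
#'   (eosin pink), `cytoplasm` (pale mucin), `nucleus` (haematoxylin
#'   purple), `distractor` (darker stromal red), plus `jitter`, the
#'   per-cell uniform colour jitter amplitude.
#' @param crescent_fraction fraction of the rim circumference covered by
#'   the crescent nucleus (default 0.45).
#' @param n_distractors unannotated elliptical blobs (default 4).
#' @param noise_sigma additive Gaussian intensity noise sd (default 0.02).
#' @param blur_sigma Gaussian blur sd in pixels applied last (default 0.6).
#' @param min_separation required centre distance between two cells as a
#'   multiple of their radius sum (default 1.05, i.e. non-overlapping).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(seed = 1L, size = c(128L, 128L), n_cells = 3L,
                       radius_range = c(8, 16),
                       palette = list(background = c(0.91, 0.76, 0.82),
                                      cytoplasm = c(0.97, 0.95, 0.98),
                                      nucleus = c(0.38, 0.22, 0.52),
                                      distractor = c(0.75, 0.45, 0.55),
                                      jitter = 0.04),
                       crescent_fraction = 0.45, n_distractors = 4L,
                       noise_sigma = 0.02, blur_sigma = 0.6,
                       min_separation = 1.05) {
  stopifnot(length(size) == 2, n_cells >= 0, noise_sigma >= 0, blur_sigma >= 0,
            radius_range[1] > 0, radius_range[2] >= radius_range[1],
            radius_range[2] < min(size) / 2)
  structure(list(seed = as.integer(seed), size = as.integer(size),
                 n_cells = as.integer(n_cells), radius_range = radius_range,
                 palette = palette, crescent_fraction = crescent_fraction,
                 n_distractors = as.integer(n_distractors),
                 noise_sigma = noise_sigma, blur_sigma = blur_sigma,
                 min_separation = min_separation),
            class = "scene_spec")
}

# Alpha-blend a colour onto the image where `alpha` (H x W in [0,1]) covers.
blend <- function(img, alpha, col) {
  for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - alpha) + col[ch] * alpha
  img
}

# Soft-edged disk coverage: 1 inside, linear 1-px falloff at the boundary.
disk_alpha <- function(dist, r) pmin(1, pmax(0, r + 0.5 - dist))

#' Generate one synthetic tile with exact circle annotations
#'
#' Renders the scene described by a [scene_spec()]: a textured background,
#' `n_cells` non-overlapping ring cells (pale cytoplasm disk, darker rim,
#' crescent nucleus hugging the rim), unannotated distractor ellipses, then
#' additive Gaussian noise and blur. The returned annotations are exactly
#' the drawn disks.
#'
#' @param spec a [scene_spec()].
#' @return List with `image` (array `H x W x 3` in `[0, 1]`) and
#'   `annotations` (data frame `cx`, `cy`, `r`, `class_id`).
#' @export
generate_scene <- function(spec = scene_spec()) {
  set.seed(spec$seed)
  H <- spec$size[1]; W <- spec$size[2]
  pal <- spec$palette
  jit <- function(col) pmin(1, pmax(0, col + runif(3, -pal$jitter, pal$jitter)))

  # background: base colour + smooth low-frequency texture
  img <- array(rep(pal$background, each = H * W), c(H, W, 3))
  coarse <- array(runif(8 * 8 * 3, -0.035, 0.035), c(8, 8, 3))
  for (ch in 1:3) {
    tex <- EBImage::resize(coarse[, , ch], w = H, h = W)
    img[, , ch] <- img[, , ch] + tex
  }

  # x = column, y = row, 0-based pixel centres
  gx <- matrix(rep(0:(W - 1), each = H), H, W)
  gy <- matrix(rep(0:(H - 1), W), H, W)

  # place cells by rejection sampling under the separation constraint
  cells <- data.frame()
  trials <- 0
  while (nrow(cells) < spec$n_cells) {
    if (trials > 200 * max(1, spec$n_cells))
      stop("could not place ", spec$n_cells, " cells after ", trials,
           " trials; reduce n_cells or the radius range")
    trials <- trials + 1
    r <- runif(1, spec$radius_range[1], spec$radius_range[2])
    cx <- runif(1, r + 2, W - 1 - r - 2)
    cy <- runif(1, r + 2, H - 1 - r - 2)
    if (nrow(cells) > 0) {
      d <- sqrt((cells$cx - cx)^2 + (cells$cy - cy)^2)
      if (any(d < spec$min_separation * (cells$r + r))) next
    }
    cells <- rbind(cells, data.frame(cx = cx, cy = cy, r = r))
  }

  for (k in seq_len(nrow(cells))) {
    cx <- cells$cx[k]; cy <- cells$cy[k]; r <- cells$r[k]
    dist <- sqrt((gx - cx)^2 + (gy - cy)^2)
    img <- blend(img, disk_alpha(dist, r), jit(pal$cytoplasm))
    rim <- disk_alpha(dist, r) * (1 - disk_alpha(dist, r - 1.5))
    img <- blend(img, rim * 0.6, pal$nucleus * 0.5 + pal$background * 0.5)
    # crescent nucleus along the rim
    theta0 <- runif(1, -pi, pi)
    ang <- atan2(gy - cy, gx - cx)
    dang <- abs(((ang - theta0 + pi) %% (2 * pi)) - pi)
    cres <- disk_alpha(dist, 0.95 * r) * (1 - disk_alpha(dist, 0.5 * r)) *
      (dang <= spec$crescent_fraction * pi)
    img <- blend(img, cres, jit(pal$nucleus))
  }

  # unannotated distractor ellipses, kept clear of the cells
  placed <- 0; trials <- 0
  while (placed < spec$n_distractors && trials < 200 * max(1, spec$n_distractors)) {
    trials <- trials + 1
    a <- runif(1, 2, 5); b <- runif(1, 2, 5); phi <- runif(1, 0, pi)
    dx <- runif(1, 6, W - 7); dy <- runif(1, 6, H - 7)
    if (nrow(cells) > 0 &&
        any(sqrt((cells$cx - dx)^2 + (cells$cy - dy)^2) < cells$r + max(a, b) + 2))
      next
    xr <- (gx - dx) * cos(phi) + (gy - dy) * sin(phi)
    yr <- -(gx - dx) * sin(phi) + (gy - dy) * cos(phi)
    ed <- sqrt((xr / a)^2 + (yr / b)^2)
    img <- blend(img, pmin(1, pmax(0, (1 - ed) * max(a, b) + 0.5)), jit(pal$distractor))
    placed <- placed + 1
  }

  if (spec$noise_sigma > 0)
    img <- img + array(rnorm(H * W * 3, 0, spec$noise_sigma), c(H, W, 3))
  if (spec$blur_sigma > 0)
    for (ch in 1:3) img[, , ch] <- EBImage::gblur(img[, , ch], spec$blur_sigma)
  img <- pmin(pmax(img, 0), 1)
  dim(img) <- c(H, W, 3)

  anns <- if (nrow(cells)) cbind(cells, class_id = 1L) else
    data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0),
               class_id = integer(0))
  list(image = img, annotations = anns)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_pos` positive tiles (1 to `max_cells` cells each) and `n_neg`
#' negative tiles (no cells), with PNG images, an `annotations.csv`, and a
#' `manifest.csv` carrying a stratified train/test split at `split_ratio`.
#' Per-image seeds are drawn once from the master seed, so the dataset is a
#' pure function of its arguments.
#'
#' @param out_dir output directory (created; must be empty unless
#'   `overwrite = TRUE`).
#' @param n_pos,n_neg number of positive / negative tiles.
#' @param template a [scene_spec()] supplying everything but seed and cell
#'   count.
#' @param seed master seed.
#' @param max_cells maximum cells per positive tile (default 5).
#' @param split_ratio train fraction (default 0.7).
#' @param overwrite allow writing into a non-empty directory.
#' @return The manifest data frame (invisibly written to disk too).
#' @export
generate_dataset <- function(out_dir, n_pos, n_neg, template = scene_spec(),
                             seed = 1L, max_cells = 5L, split_ratio = 0.7,
                             overwrite = FALSE) {
  stopifnot(n_pos >= 0, n_neg >= 0, n_pos + n_neg > 0)
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("output directory ", out_dir, " is not empty (use overwrite = TRUE)")
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)

  n <- n_pos + n_neg
  set.seed(seed)
  img_seeds <- sample.int(.Machine$integer.max - 1L, n)
  n_cells <- c(sample(seq_len(max_cells), n_pos, replace = TRUE), rep(0L, n_neg))
  label <- c(rep("positive", n_pos), rep("negative", n_neg))

  anns <- list(); man <- list()
  for (i in seq_len(n)) {
    spec <- template
    spec$seed <- img_seeds[i]
    spec$n_cells <- n_cells[i]
    sc <- generate_scene(spec)
    file <- sprintf("images/tile_%04d.png", i)
    save_image_png(sc$image, file.path(out_dir, file))
    if (nrow(sc$annotations))
      anns[[length(anns) + 1]] <- cbind(file = file, sc$annotations)
    man[[i]] <- data.frame(file = file, label = label[i],
                           n_cells = n_cells[i], seed = img_seeds[i])
  }
  man <- do.call(rbind, man)
  man$split <- assign_split(man, split_ratio, seed)
  anns <- if (length(anns)) do.call(rbind, anns) else
    data.frame(file = character(0), cx = numeric(0), cy = numeric(0),
               r = numeric(0), class_id = integer(0))
  write_annotations_csv(anns, file.path(out_dir, "annotations.csv"))
  write_manifest(man, file.path(out_dir, "manifest.csv"))
  man
}
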
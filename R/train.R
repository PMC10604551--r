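# Adam optimiser over parameter references (layer environments are mutated
# in place). SGD with momentum is available as a fallback.
optimizer_init <- function(refs, name = "adam", lr = 1e-3,
                           beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                           momentum = 0.9) {
  st <- list(refs = refs, name = name, lr = lr, beta1 = beta1, beta2 = beta2,
             eps = eps, momentum = momentum, t = 0,
             m = lapply(refs, function(r) r$layer$params[[r$name]] * 0),
             v = if (name == "adam")
               lapply(refs, function(r) r$layer$params[[r$name]] * 0))
  structure(st, class = "cn_optimizer")
}

optimizer_step <- function(opt) {
  opt$t <- opt$t + 1
  for (i in seq_along(opt$refs)) {
    r <- opt$refs[[i]]
    g <- r$layer$grads[[r$name]]
    if (is.null(g)) next
    if (opt$name == "adam") {
      opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
      opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g^2
      mhat <- opt$m[[i]] / (1 - opt$beta1^opt$t)
      vhat <- opt$v[[i]] / (1 - opt$beta2^opt$t)
      upd <- opt$lr * mhat / (sqrt(vhat) + opt$eps)
    } else {
      opt$m[[i]] <- opt$momentum * opt$m[[i]] + g
      upd <- opt$lr * opt$m[[i]]
    }
    p <- r$layer$params[[r$name]] - upd
    attributes(p) <- attributes(r$layer$params[[r$name]])
    r$layer$params[[r$name]] <- p
  }
  opt
}

#' Training configuration
#'
#' @param learning_rate optimiser step size (default 0.001).
#' @param batch_size images per gradient step (default 32).
#' @param epochs training epochs (default 25).
#' @param split_ratio train fraction used when a manifest has no split
#'   column (default 0.7, i.e. a 70:30 split).
#' @param seed master seed controlling weight init and data order.
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param lr_decay_epoch epoch after which the learning rate is multiplied
#'   by `lr_decay_factor` (standard step schedule; `Inf` disables). The
#'   default decays for the last fifth of training.
#' @param lr_decay_factor multiplier applied at `lr_decay_epoch` (default 0.1).
#' @param backbone a [backbone_config()].
#' @param codec a [codec_config()].
#' @param weights a [loss_weights()].
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 32L, epochs = 25L,
                         split_ratio = 0.7, seed = 1L, optimizer = "adam",
                         lr_decay_epoch = ceiling(0.8 * epochs),
                         lr_decay_factor = 0.1,
                         backbone = backbone_config(), codec = codec_config(),
                         weights = loss_weights()) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1,
            split_ratio > 0, split_ratio < 1,
            optimizer %in% c("adam", "sgd"), lr_decay_factor > 0)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), split_ratio = split_ratio,
                 seed = as.integer(seed), optimizer = optimizer,
                 lr_decay_epoch = lr_decay_epoch,
                 lr_decay_factor = lr_decay_factor,
                 backbone = backbone, codec = codec, weights = weights),
            class = "train_config")
}

# One optimisation step on a batch already assembled as arrays.
train_step <- function(net, opt, xb, targets_list, w) {
  out <- network_forward(net, xb, training = TRUE)
  B <- dim(xb)[4]
  gh <- out$heatmap * 0; go <- out$offset * 0; gr <- out$radius * 0
  comp <- c(heatmap = 0, radius = 0, offset = 0, total = 0)
  for (b in seq_len(B)) {
    S <- dim(out$heatmap)[3]
    ph <- out$heatmap[, , , b, drop = FALSE]; dim(ph) <- dim(out$heatmap)[1:3]
    po <- out$offset[, , , b, drop = FALSE]; dim(po) <- dim(out$offset)[1:3]
    pr <- out$radius[, , 1, b]
    dl <- detection_loss(ph, po, pr, targets_list[[b]], w)
    gh[, , , b] <- dl$grad_heatmap / B
    go[, , , b] <- dl$grad_offset / B
    gr[, , 1, b] <- dl$grad_radius / B
    comp <- comp + c(dl$heatmap, dl$radius, dl$offset, dl$total) / B
  }
  network_backward(net, gh, go, gr)
  opt <- optimizer_step(opt)
  list(opt = opt, losses = comp)
}

#' Train the circle detection network
#'
#' Runs the seeded training loop: images in the manifest's train split are
#' encoded into heatmap/offset/radius targets, batches are drawn in a
#' seed-determined order, and the multi-task loss is minimised with Adam (or
#' SGD) at a constant learning rate. Per-epoch component losses are logged
#' as JSON lines and returned.
#'
#' @param data_dir dataset directory containing `manifest.csv`,
#'   `annotations.csv` and the images (see [generate_dataset()]).
#' @param cfg a [train_config()].
#' @param checkpoint_path where to write the final checkpoint (default
#'   `checkpoint.rds` inside `data_dir`); the best-loss checkpoint is
#'   written next to it as `*_best.rds`.
#' @param log_path optional JSON-lines file of per-epoch losses.
#' @param quiet suppress per-epoch console messages.
#' @return List with `net` (the trained model), `history` (data frame of
#'   per-epoch losses) and `checkpoint_path`.
#' @export
train_circlenet <- function(data_dir, cfg = train_config(),
                            checkpoint_path = file.path(data_dir, "checkpoint.rds"),
                            log_path = NULL, quiet = FALSE) {
  man <- read_manifest(file.path(data_dir, "manifest.csv"))
  anns <- read_annotations_csv(file.path(data_dir, "annotations.csv"))
  if (!"split" %in% names(man))
    man$split <- assign_split(man, cfg$split_ratio, cfg$seed)
  tr <- man[man$split == "train", , drop = FALSE]
  if (nrow(tr) == 0) stop("manifest has no training images")

  set.seed(cfg$seed)
  net <- build_network(cfg$backbone, cfg$codec)
  refs <- unlist(lapply(net_modules(net), collect_param_refs), recursive = FALSE)
  opt <- optimizer_init(refs, cfg$optimizer, lr = cfg$learning_rate)

  imgs <- vector("list", nrow(tr))
  tgts <- vector("list", nrow(tr))
  for (i in seq_len(nrow(tr))) {
    img <- load_image_png(file.path(data_dir, tr$file[i]))
    a <- anns[anns$file == tr$file[i], , drop = FALSE]
    imgs[[i]] <- img
    tgts[[i]] <- encode_targets(a, dim(img)[1:2], cfg$codec)
  }
  H <- dim(imgs[[1]])[1]; W <- dim(imgs[[1]])[2]

  history <- data.frame()
  best <- Inf
  best_path <- sub("\\.rds$", "_best.rds", checkpoint_path)
  for (ep in seq_len(cfg$epochs)) {
    if (is.finite(cfg$lr_decay_epoch) && ep == cfg$lr_decay_epoch + 1)
      opt$lr <- opt$lr * cfg$lr_decay_factor
    ord <- sample(length(imgs))
    nb <- ceiling(length(ord) / cfg$batch_size)
    ep_loss <- c(heatmap = 0, radius = 0, offset = 0, total = 0)
    for (bi in seq_len(nb)) {
      sel <- ord[((bi - 1) * cfg$batch_size + 1):min(bi * cfg$batch_size, length(ord))]
      xb <- array(0, c(H, W, 3, length(sel)))
      for (j in seq_along(sel)) xb[, , , j] <- imgs[[sel[j]]]
      st <- train_step(net, opt, xb, tgts[sel], cfg$weights)
      opt <- st$opt
      if (!all(is.finite(st$losses)))
        stop("non-finite loss at epoch ", ep, ", batch ", bi,
             " - lower the learning rate")
      ep_loss <- ep_loss + st$losses * length(sel) / length(ord)
    }
    row <- data.frame(epoch = ep, loss = ep_loss[["total"]],
                      heatmap = ep_loss[["heatmap"]], radius = ep_loss[["radius"]],
                      offset = ep_loss[["offset"]])
    history <- rbind(history, row)
    if (!quiet)
      message(sprintf("epoch %3d  loss %.4f  (heat %.4f  radius %.4f  offset %.4f)",
                      ep, row$loss, row$heatmap, row$radius, row$offset))
    if (!is.null(log_path))
      cat(jsonlite::toJSON(as.list(row), auto_unbox = TRUE), "\n",
          file = log_path, append = ep > 1)
    if (ep_loss[["total"]] < best) {
      best <- ep_loss[["total"]]
      save_checkpoint(net, best_path)
    }
  }
  save_checkpoint(net, checkpoint_path)
  list(net = net, history = history, checkpoint_path = checkpoint_path)
}

# Stratified-by-label train/test assignment at the configured ratio.
assign_split <- function(man, ratio, seed) {
  set.seed(seed)
  split <- rep("test", nrow(man))
  for (lab in unique(man$label)) {
    idx <- which(man$label == lab)
    n_tr <- round(length(idx) * ratio)
    split[sample(idx, n_tr)] <- "train"
  }
  split
}

#' Run detection on images
#'
#' Loads a trained model, forwards each image, decodes peaks into circle
#' detections (optional NMS) and returns/writes a prediction table.
#'
#' @param model a trained model or a checkpoint path.
#' @param images character vector of image paths, or a dataset directory
#'   whose manifest (test split, if present) is used.
#' @param out_csv optional path for the predictions CSV.
#' @param split manifest split to use when `images` is a directory
#'   (default `"test"`; `NULL` for all).
#' @param nms,nms_thresh non-maximum suppression settings.
#' @param score_threshold optional override of the codec's confidence floor
#'   (use a low value such as 0.05 when the detections feed a
#'   precision-recall evaluation, so the full curve is swept).
#' @return Detection data frame with columns `file`, `cx`, `cy`, `r`,
#'   `class_id`, `score`.
#' @export
detect_circles <- function(model, images, out_csv = NULL, split = "test",
                           nms = TRUE, nms_thresh = 0.5,
                           score_threshold = NULL) {
  net <- if (is.character(model)) load_checkpoint(model) else model
  if (!is.null(score_threshold)) net$codec$score_threshold <- score_threshold
  base_dir <- ""
  if (length(images) == 1 && dir.exists(images)) {
    man <- read_manifest(file.path(images, "manifest.csv"))
    if (!is.null(split) && "split" %in% names(man))
      man <- man[man$split == split, , drop = FALSE]
    base_dir <- images
    images <- man$file
  }
  out <- vector("list", length(images))
  for (i in seq_along(images)) {
    img <- load_image_png(file.path(base_dir, images[i]))
    o <- network_forward(net, img, training = FALSE)
    hm <- o$heatmap; dim(hm) <- dim(hm)[1:3]
    off <- o$offset; dim(off) <- dim(off)[1:3]
    dets <- decode_detections(hm, off, o$radius[, , 1, 1],
                              net$codec, nms = nms, nms_thresh = nms_thresh)
    if (nrow(dets)) dets <- cbind(file = images[i], dets)
    out[[i]] <- dets
  }
  preds <- do.call(rbind, out[vapply(out, nrow, 1L) > 0])
  if (is.null(preds))
    preds <- data.frame(file = character(0), cx = numeric(0), cy = numeric(0),
                        r = numeric(0), class_id = integer(0), score = numeric(0))
  rownames(preds) <- NULL
  attr(preds, "images") <- images
  if (!is.null(out_csv)) write_annotations_csv(preds, out_csv)
  preds
}
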
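#' Backbone configuration
#'
#' Describes the modified ResNet-34 feature extractor: a full-resolution stem
#' of three stacked 3x3 convolutions followed by a CBAM attention block
#' (replacing the conventional 7x7 stride-2 convolution), a 3x3/2 max pool,
#' and four residual stages whose channel width doubles per stage, giving a
#' total encoder stride of 32.
#'
#' @param stage_blocks integer vector of residual blocks per stage
#'   (default `c(3, 4, 6, 3)`, the ResNet-34 layout).
#' @param base_channels stem and first-stage width (default 64).
#' @param cbam_reduction channel-attention bottleneck ratio (default 16).
#' @param cbam_spatial_kernel spatial-attention kernel size, odd (default 7).
#' @param tiny if `TRUE`, defaults shrink to one block per stage and 16 base
#'   channels — a reduced variant for CPU-scale experiments.
#' @return An object of class `backbone_config`.
#' @export
backbone_config <- function(stage_blocks = NULL, base_channels = NULL,
                            cbam_reduction = 16L, cbam_spatial_kernel = 7L,
                            tiny = FALSE) {
  if (is.null(stage_blocks)) stage_blocks <- if (tiny) c(1L, 1L, 1L, 1L) else c(3L, 4L, 6L, 3L)
  if (is.null(base_channels)) base_channels <- if (tiny) 16L else 64L
  stopifnot(length(stage_blocks) == 4, all(stage_blocks >= 1),
            base_channels >= 1, cbam_reduction >= 1,
            cbam_spatial_kernel %% 2 == 1)
  structure(list(stage_blocks = as.integer(stage_blocks),
                 base_channels = as.integer(base_channels),
                 cbam_reduction = as.integer(cbam_reduction),
                 cbam_spatial_kernel = as.integer(cbam_spatial_kernel),
                 tiny = tiny),
            class = "backbone_config")
}

#' Residual block constructor
#'
#' Two 3x3 convolutions with batch normalisation and rectified activation,
#' added to the identity shortcut (`Z = M(y) + y`); a 1x1 projection aligns
#' the shortcut when the stride or channel count changes. Apply with
#' [apply_block()].
#'
#' @param cin,cout input and output channels.
#' @param stride 1 or 2 (stride 2 halves the spatial dimensions).
#' @return A block object.
#' @export
residual_block <- function(cin, cout = cin, stride = 1L)
  nn_residual(cin, cout, stride)

#' CBAM attention block constructor
#'
#' Sequential channel and spatial attention: the feature map is scaled by a
#' per-channel sigmoid gate (shared two-layer bottleneck over global average-
#' and max-pooled descriptors) and then by a per-pixel sigmoid gate (a
#' convolution over the channel-wise mean and max maps). Output shape equals
#' input shape. Apply with [apply_block()].
#'
#' @param channels feature channels.
#' @param reduction bottleneck ratio (default 16).
#' @param spatial_kernel odd spatial-attention kernel size (default 7).
#' @return A block object.
#' @export
cbam_block <- function(channels, reduction = 16L, spatial_kernel = 7L)
  nn_cbam(channels, reduction, spatial_kernel)

#' Apply a network block to a feature map
#'
#' @param block a block from [residual_block()], [cbam_block()] or an
#'   internal layer.
#' @param x array `H x W x C` (one sample) or `H x W x C x N`.
#' @param training use batch statistics in normalisation layers (default
#'   `FALSE`).
#' @return The transformed feature map, same arity as the input.
#' @export
apply_block <- function(block, x, training = FALSE) {
  single <- length(dim(x)) == 3
  if (single) dim(x) <- c(dim(x), 1)
  y <- layer_forward(block, x, training)
  if (single) dim(y) <- dim(y)[1:3]
  y
}

#' Build the circle detection network
#'
#' Assembles stem (+CBAM), max pool, four residual stages (total stride 32),
#' a transposed-convolution decoder back to the codec stride, and three
#' prediction heads (heatmap with sigmoid, offset, radius), each a 3x3
#' convolution with 64 channels followed by a 1x1 convolution. The heatmap
#' head's final bias starts at -2.19 so the initial foreground probability is
#' about 0.1, which keeps the focal loss stable early in training.
#'
#' @param cfg a [backbone_config()].
#' @param codec a [codec_config()]; its `stride` must be `32 / 2^k` for an
#'   integer number of decoder stages `k`.
#' @param seed optional integer seed for weight initialisation.
#' @return An object of class `circle_network`.
#' @export
build_network <- function(cfg = backbone_config(), codec = codec_config(),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_up <- log2(32 / codec$stride)
  if (n_up != round(n_up) || n_up < 0)
    stop("codec stride must be 32 / 2^k for integer k >= 0")
  C <- cfg$base_channels
  stem <- nn_sequential(
    nn_conv(3L, C), nn_bn(C), nn_relu(),
    nn_conv(C, C), nn_bn(C), nn_relu(),
    nn_conv(C, C), nn_bn(C), nn_relu(),
    nn_cbam(C, cfg$cbam_reduction, cfg$cbam_spatial_kernel),
    nn_maxpool())
  widths <- C * c(1L, 2L, 4L, 8L)
  stages <- vector("list", 4)
  cin <- C
  for (s in 1:4) {
    blocks <- list(nn_residual(cin, widths[s], stride = 2L))
    if (cfg$stage_blocks[s] > 1)
      for (b in 2:cfg$stage_blocks[s])
        blocks[[b]] <- nn_residual(widths[s], widths[s])
    stages[[s]] <- nn_sequential(blocks)
    cin <- widths[s]
  }
  dec <- list()
  dc <- cin
  for (u in seq_len(n_up)) {
    dout <- max(C, dc %/% 2L)
    dec <- c(dec, list(nn_convt(dc, dout), nn_bn(dout), nn_relu()))
    dc <- dout
  }
  decoder <- nn_sequential(dec)
  head <- function(nout, bias_init = 0) nn_sequential(
    nn_conv(dc, 64L), nn_relu(),
    nn_conv(64L, nout, k = 1L, pad = 0L, init_sd = 0.01, bias_init = bias_init))
  net <- new.env(parent = emptyenv())
  net$backbone <- cfg
  net$codec <- codec
  net$stem <- stem
  net$stages <- stages
  net$decoder <- decoder
  net$head_heatmap <- head(codec$num_classes, bias_init = -2.19)
  net$head_offset <- head(2L)
  net$head_radius <- head(1L)
  class(net) <- "circle_network"
  net
}

net_modules <- function(net)
  c(list(net$stem), net$stages,
    list(net$decoder, net$head_heatmap, net$head_offset, net$head_radius))

#' Forward pass of the detection network
#'
#' @param net a [build_network()] model.
#' @param x image array `H x W x 3` or batch `H x W x 3 x N`, values in
#'   `[0, 1]`; `H` and `W` must be divisible by 32.
#' @param training use batch statistics in normalisation layers.
#' @return List with `heatmap` (`H/R x W/R x classes x N`, sigmoid
#'   activated), `offset` (`... x 2 x N`) and `radius` (`... x 1 x N`).
#' @export
network_forward <- function(net, x, training = FALSE) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  d <- dim(x)
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0)
    stop("input size (", d[1], "x", d[2], ") must be divisible by 32")
  f <- layer_forward(net$stem, x, training)
  for (s in net$stages) f <- layer_forward(s, f, training)
  f <- layer_forward(net$decoder, f, training)
  logits <- layer_forward(net$head_heatmap, f, training)
  prob <- sigmoid(logits)
  net$.heat_prob <- prob
  list(heatmap = prob,
       offset = layer_forward(net$head_offset, f, training),
       radius = layer_forward(net$head_radius, f, training))
}

# Backward pass: gradients are wrt the three output maps (heatmap gradient
# wrt the sigmoid-activated probabilities). Fills layer grads for the
# optimiser; the gradient wrt the input image is discarded.
network_backward <- function(net, grad_heatmap, grad_offset, grad_radius) {
  p <- net$.heat_prob
  dlogits <- grad_heatmap * p * (1 - p)
  df <- layer_backward(net$head_heatmap, dlogits) +
    layer_backward(net$head_offset, grad_offset) +
    layer_backward(net$head_radius, grad_radius)
  df <- layer_backward(net$decoder, df)
  for (s in rev(net$stages)) df <- layer_backward(s, df)
  invisible(layer_backward(net$stem, df))
}

#' Number of trainable parameters
#'
#' @param net a [build_network()] model.
#' @return Integer parameter count.
#' @export
count_parameters <- function(net) {
  refs <- unlist(lapply(net_modules(net), collect_param_refs), recursive = FALSE)
  sum(vapply(refs, function(r) length(r$layer$params[[r$name]]), numeric(1)))
}

# Full state (weights + batchnorm running statistics) in traversal order.
net_state <- function(net) {
  state <- list()
  walk <- function(l) {
    state[[length(state) + 1]] <<- c(l$params,
      if (l$type == "bn") list(.rm = l$running_mean, .rv = l$running_var))
    if (l$type == "sequential") for (sub in l$layers) walk(sub)
    if (l$type == "residual") {
      walk(l$conv1); walk(l$bn1); walk(l$conv2); walk(l$bn2)
      if (!is.null(l$proj)) { walk(l$proj$conv); walk(l$proj$bn) }
    }
  }
  for (m in net_modules(net)) walk(m)
  state
}

net_restore <- function(net, state) {
  i <- 0
  walk <- function(l) {
    i <<- i + 1
    s <- state[[i]]
    if (l$type == "bn") {
      l$running_mean <- s$.rm; l$running_var <- s$.rv
      s$.rm <- NULL; s$.rv <- NULL
    }
    if (length(l$params)) l$params <- s[names(l$params)]
    if (l$type == "sequential") for (sub in l$layers) walk(sub)
    if (l$type == "residual") {
      walk(l$conv1); walk(l$bn1); walk(l$conv2); walk(l$bn2)
      if (!is.null(l$proj)) { walk(l$proj$conv); walk(l$proj$bn) }
    }
  }
  for (m in net_modules(net)) walk(m)
  invisible(net)
}

#' Save / load a model checkpoint
#'
#' A checkpoint bundles the backbone and codec configurations with all
#' weights and normalisation statistics in a single file.
#'
#' @param net a [build_network()] model.
#' @param path file path (".rds").
#' @return `load_checkpoint()` returns the restored model.
#' @export
save_checkpoint <- function(net, path) {
  for (m in net_modules(net)) clear_caches(m)
  saveRDS(list(backbone = net$backbone, codec = net$codec,
               state = net_state(net)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- build_network(ck$backbone, ck$codec, seed = 0L)
  net_restore(net, ck$state)
  net
}
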
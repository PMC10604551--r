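# Minimal layer framework used by the detector network.
#
# A layer is an environment holding `params` (named list of arrays), `grads`
# (filled by the backward pass) and whatever forward caches the backward pass
# needs. Tensors are dense arrays dim = c(H, W, C, N). Dispatch is by
# `l$type` through layer_forward() / layer_backward(); parameters are
# gathered by reference with collect_param_refs() for the optimiser.
# Heavy ops (conv, transposed conv, max pool) run in compiled code.

new_layer <- function(type, params = list(), fields = list()) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  l$params <- params
  l$grads <- list()
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = l)
  class(l) <- c(paste0("nn_", type), "nn_layer")
  l
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# He-style fan-in init for conv weights, optionally overridden for heads.
conv_init <- function(k, cin, cout, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / (k * k * cin))
  array(rnorm(k * k * cin * cout, 0, sd), c(k, k, cin, cout))
}

nn_conv <- function(cin, cout, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L,
                    init_sd = NULL, bias_init = 0) {
  new_layer("conv",
            params = list(w = conv_init(k, cin, cout, init_sd),
                          b = rep(bias_init, cout)),
            fields = list(stride = as.integer(stride), pad = as.integer(pad)))
}

nn_convt <- function(cin, cout, k = 4L, stride = 2L, pad = 1L) {
  sd <- sqrt(2 / (k * k * cin))
  new_layer("convt",
            params = list(w = array(rnorm(k * k * cout * cin, 0, sd),
                                    c(k, k, cout, cin)),
                          b = rep(0, cout)),
            fields = list(stride = as.integer(stride), pad = as.integer(pad)))
}

nn_bn <- function(C, momentum = 0.1, eps = 1e-5) {
  new_layer("bn",
            params = list(gamma = rep(1, C), beta = rep(0, C)),
            fields = list(running_mean = rep(0, C), running_var = rep(1, C),
                          momentum = momentum, eps = eps))
}

nn_relu <- function() new_layer("relu")

nn_maxpool <- function(k = 3L, stride = 2L, pad = 1L)
  new_layer("maxpool", fields = list(k = as.integer(k), stride = as.integer(stride),
                                     pad = as.integer(pad)))

nn_cbam <- function(C, reduction = 16L, spatial_kernel = 7L) {
  if (spatial_kernel %% 2 != 1) stop("CBAM spatial kernel must be odd")
  cr <- max(1L, C %/% as.integer(reduction))
  sd1 <- sqrt(2 / C); sd2 <- sqrt(2 / cr)
  new_layer("cbam",
            params = list(w1 = matrix(rnorm(cr * C, 0, sd1), cr, C),
                          b1 = rep(0, cr),
                          w2 = matrix(rnorm(C * cr, 0, sd2), C, cr),
                          b2 = rep(0, C),
                          ws = conv_init(spatial_kernel, 2L, 1L),
                          bs = 0),
            fields = list(k = as.integer(spatial_kernel)))
}

nn_sequential <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && is.list(layers[[1]]) && !inherits(layers[[1]], "nn_layer"))
    layers <- layers[[1]]
  new_layer("sequential", fields = list(layers = layers))
}

# Basic residual block: conv-bn-relu-conv-bn + identity (1x1 projection when
# shape changes), final relu after the addition.
nn_residual <- function(cin, cout, stride = 1L) {
  proj <- if (stride != 1 || cin != cout)
    list(conv = nn_conv(cin, cout, k = 1L, stride = stride, pad = 0L),
         bn = nn_bn(cout))
  new_layer("residual",
            fields = list(conv1 = nn_conv(cin, cout, k = 3L, stride = stride),
                          bn1 = nn_bn(cout), conv2 = nn_conv(cout, cout, k = 3L),
                          bn2 = nn_bn(cout), proj = proj))
}

# ---- forward / backward dispatch ------------------------------------------

layer_forward <- function(l, x, training = TRUE) {
  switch(l$type,
    conv = {
      l$x <- x
      cn_conv2d_forward(x, l$params$w, l$params$b, l$stride, l$pad)
    },
    convt = {
      l$x <- x
      cn_convt2d_forward(x, l$params$w, l$params$b, l$stride, l$pad)
    },
    relu = {
      y <- cn_relu_forward(x)
      l$y <- y
      y
    },
    maxpool = {
      d <- dim(x)
      res <- cn_maxpool_forward(x, l$k, l$stride, l$pad)
      l$idx <- res$idx; l$in_h <- d[1]; l$in_w <- d[2]
      res$y
    },
    bn = bn_forward(l, x, training),
    cbam = cbam_forward(l, x),
    sequential = {
      for (sub in l$layers) x <- layer_forward(sub, x, training)
      x
    },
    residual = {
      main <- layer_forward(l$bn1, layer_forward(l$conv1, x, training), training)
      main <- cn_relu_forward(main)
      l$a1 <- main
      main <- layer_forward(l$bn2, layer_forward(l$conv2, main, training), training)
      short <- if (is.null(l$proj)) x else
        layer_forward(l$proj$bn, layer_forward(l$proj$conv, x, training), training)
      y <- cn_relu_forward(main + short)
      l$y <- y
      y
    },
    stop("unknown layer type: ", l$type))
}

layer_backward <- function(l, dy) {
  switch(l$type,
    conv = {
      g <- cn_conv2d_backward(l$x, l$params$w, dy, l$stride, l$pad)
      l$grads <- list(w = g$dw, b = g$db)
      g$dx
    },
    convt = {
      g <- cn_convt2d_backward(l$x, l$params$w, dy, l$stride, l$pad)
      l$grads <- list(w = g$dw, b = g$db)
      g$dx
    },
    relu = cn_relu_backward(l$y, dy),
    maxpool = cn_maxpool_backward(dy, l$idx, l$in_h, l$in_w),
    bn = bn_backward(l, dy),
    cbam = cbam_backward(l, dy),
    sequential = {
      for (sub in rev(l$layers)) dy <- layer_backward(sub, dy)
      dy
    },
    residual = {
      ds <- cn_relu_backward(l$y, dy)
      dmain <- layer_backward(l$conv2, layer_backward(l$bn2, ds))
      dmain <- cn_relu_backward(l$a1, dmain)
      dx <- layer_backward(l$conv1, layer_backward(l$bn1, dmain))
      dshort <- if (is.null(l$proj)) ds else
        layer_backward(l$proj$conv, layer_backward(l$proj$bn, ds))
      dx + dshort
    },
    stop("unknown layer type: ", l$type))
}

# ---- batch normalisation ---------------------------------------------------

# Statistics over (H, W, N) per channel; biased variance for normalisation,
# running estimates for inference. Heavy lifting in compiled code.
bn_forward <- function(l, x, training) {
  if (training) {
    st <- cn_bn_stats(x)
    mu <- st$mean; v <- st$var
    l$running_mean <- (1 - l$momentum) * l$running_mean + l$momentum * mu
    l$running_var <- (1 - l$momentum) * l$running_var + l$momentum * v
  } else {
    mu <- l$running_mean; v <- l$running_var
  }
  ivar <- 1 / sqrt(v + l$eps)
  if (training) { l$x <- x; l$mu <- mu; l$ivar <- ivar }
  cn_bn_apply(x, mu, ivar, l$params$gamma, l$params$beta)
}

bn_backward <- function(l, dy) {
  g <- cn_bn_backward(l$x, dy, l$mu, l$ivar, l$params$gamma)
  l$grads <- list(gamma = g$dgamma, beta = g$dbeta)
  g$dx
}

# ---- CBAM ------------------------------------------------------------------

# Channel gate: sigmoid(MLP(avgpool) + MLP(maxpool)), shared two-layer MLP,
# applied per channel. Spatial gate: sigmoid(conv_k(channel mean/max maps)),
# applied per pixel. Backward differentiates through both gates.
cbam_forward <- function(l, x) {
  d <- dim(x); C <- d[3]; N <- d[4]
  cs <- cn_channel_stats(x)
  A <- matrix(cs$avg, C, N); M <- matrix(cs$max, C, N)
  h_a <- pmax(l$params$w1 %*% A + l$params$b1, 0)
  h_m <- pmax(l$params$w1 %*% M + l$params$b1, 0)
  z <- l$params$w2 %*% h_a + l$params$w2 %*% h_m + 2 * l$params$b2
  gate_c <- sigmoid(z)                                  # C x N
  y1 <- cn_scale_channel(x, gate_c)

  ss <- cn_spatial_stats(y1)                            # mean/max over channels
  zs <- cn_conv2d_forward(ss$stats, l$params$ws, l$params$bs, 1L, (l$k - 1L) %/% 2L)
  gate_s <- sigmoid(zs)                                 # H x W x 1 x N
  y2 <- cn_scale_spatial(y1, gate_s)

  l$cache <- list(x = x, gate_c = gate_c, A = A, M = M, h_a = h_a, h_m = h_m,
                  camax = cs$argmax, y1 = y1, stats = ss$stats,
                  gate_s = gate_s, samax = ss$argmax)
  y2
}

cbam_backward <- function(l, dy) {
  cc <- l$cache

  # spatial gate: y2 = y1 * gate_s, gate_s = sigmoid(conv(stats(y1)))
  dgate_s <- cn_spatial_dot(dy, cc$y1)
  dy1 <- cn_scale_spatial(dy, cc$gate_s)
  dzs <- dgate_s * cc$gate_s * (1 - cc$gate_s)
  g <- cn_conv2d_backward(cc$stats, l$params$ws, dzs, 1L, (l$k - 1L) %/% 2L)
  dy1 <- cn_spatial_stats_backward(dy1, g$dx, cc$samax)

  # channel gate: y1 = x * gate_c, gate_c = sigmoid(MLP(avg) + MLP(max))
  C <- nrow(cc$gate_c); N <- ncol(cc$gate_c)
  dgate_c <- matrix(cn_plane_dot(dy1, cc$x), C, N)
  dx <- cn_scale_channel(dy1, cc$gate_c)
  dz <- dgate_c * cc$gate_c * (1 - cc$gate_c)
  dh_a <- crossprod(l$params$w2, dz) * (cc$h_a > 0)
  dh_m <- crossprod(l$params$w2, dz) * (cc$h_m > 0)
  dw2 <- dz %*% t(cc$h_a) + dz %*% t(cc$h_m)
  db2 <- 2 * rowSums(dz)
  dw1 <- dh_a %*% t(cc$A) + dh_m %*% t(cc$M)
  db1 <- rowSums(dh_a) + rowSums(dh_m)
  dA <- crossprod(l$params$w1, dh_a)
  dM <- crossprod(l$params$w1, dh_m)
  dx <- cn_channel_stats_backward(dx, as.vector(dA), as.vector(dM), cc$camax)
  l$grads <- list(w1 = dw1, b1 = db1, w2 = dw2, b2 = db2, ws = g$dw, bs = g$db)
  dx
}

# ---- parameter plumbing ----------------------------------------------------

# References (layer env, parameter name) to every parameter below `l`.
collect_param_refs <- function(l) {
  refs <- list()
  add <- function(x) refs[[length(refs) + 1]] <<- x
  walk <- function(l) {
    for (nm in names(l$params)) add(list(layer = l, name = nm))
    if (l$type == "sequential") for (sub in l$layers) walk(sub)
    if (l$type == "residual") {
      walk(l$conv1); walk(l$bn1); walk(l$conv2); walk(l$bn2)
      if (!is.null(l$proj)) { walk(l$proj$conv); walk(l$proj$bn) }
    }
  }
  walk(l)
  refs
}

# Drop forward caches so checkpoints stay small.
clear_caches <- function(l) {
  for (nm in c("x", "y", "a1", "idx", "mu", "ivar", "cache"))
    if (!is.null(l[[nm]])) rm(list = nm, envir = l)
  if (l$type == "sequential") for (sub in l$layers) clear_caches(sub)
  if (l$type == "residual") {
    clear_caches(l$conv1); clear_caches(l$bn1)
    clear_caches(l$conv2); clear_caches(l$bn2)
    if (!is.null(l$proj)) { clear_caches(l$proj$conv); clear_caches(l$proj$bn) }
  }
  invisible(l)
}
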
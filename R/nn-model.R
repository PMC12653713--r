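#' Structural configuration of the deep correction network
#'
#' The deep regression network is built from two symmetric encoder-decoder
#' U-Blocks bridged by a constant-resolution M-Block, with channel
#' concatenation between blocks and a BN + 1x1 + 3x3 output head. The
#' default configuration (32 intermediate filters and 64 output channels per
#' U-Block, 32-filter / 64-channel M-Block of 8 convolutions) instantiates
#' exactly 26 convolutional layers. Downsampling is 2x2 max pooling,
#' upsampling bilinear interpolation; spatial size is restored after the two
#' upsampling passes, so inputs must have sides divisible by 4.
#'
#' @param ublock_mid_filters Intermediate filters inside each U-Block.
#' @param ublock_out_channels Output channels of each U-Block.
#' @param mblock_filters Filters inside the M-Block.
#' @param mblock_out_channels Output channels of the M-Block.
#' @param mblock_conv_layers Convolutions in the M-Block (8).
#' @param total_conv_layers Expected count of convolutional layers in the
#'   instantiated graph; the builder refuses a graph that disagrees.
#' @return A list of class `network_config`.
#' @export
network_config <- function(ublock_mid_filters = 32L,
                           ublock_out_channels = 64L,
                           mblock_filters = 32L,
                           mblock_out_channels = 64L,
                           mblock_conv_layers = 8L,
                           total_conv_layers = 26L) {
  cfg <- list(
    ublock_mid_filters = as.integer(ublock_mid_filters),
    ublock_out_channels = as.integer(ublock_out_channels),
    mblock_filters = as.integer(mblock_filters),
    mblock_out_channels = as.integer(mblock_out_channels),
    mblock_conv_layers = as.integer(mblock_conv_layers),
    total_conv_layers = as.integer(total_conv_layers)
  )
  if (any(vapply(cfg, function(v) v < 1L, logical(1)))) {
    stop("all network_config counts must be positive", call. = FALSE)
  }
  if (cfg$mblock_conv_layers < 2L) {
    stop("the M-Block needs at least 2 convolutions", call. = FALSE)
  }
  structure(cfg, class = "network_config")
}

#' Structural configuration of the shallow baseline network
#'
#' A plain 5-convolution regression network without pooling or batch
#' normalization, trained on 40x40 patches, with three scalar color
#' adjustment parameters broadcast as extra input channels.
#'
#' @param conv_layers Number of convolutions (5).
#' @param filters Filters in the hidden convolutions.
#' @param patch_size Training patch side in pixels.
#' @return A list of class `dccn_config`.
#' @export
dccn_config <- function(conv_layers = 5L, filters = 32L, patch_size = 40L) {
  cfg <- list(conv_layers = as.integer(conv_layers),
              filters = as.integer(filters),
              patch_size = as.integer(patch_size),
              adjustment_params = 3L)
  if (cfg$conv_layers < 2L || cfg$filters < 1L || cfg$patch_size < 1L) {
    stop("invalid dccn_config", call. = FALSE)
  }
  structure(cfg, class = "dccn_config")
}

# ---- U-Block: two-level encoder-decoder with concatenation skips and an
# additive residual from block input to block output. 8 convolutions. ----

ublock_init <- function(prefix, in_ch, mid, out) {
  p <- list(
    e1a = init_conv(3L, in_ch, mid),
    e1b = init_conv(3L, mid, mid),
    e2a = init_conv(3L, mid, mid),
    e2b = init_conv(3L, mid, mid),
    d1a = init_conv(3L, 2L * mid, mid),
    d1b = init_conv(3L, mid, mid),
    d2a = init_conv(3L, 2L * mid, mid),
    d2b = init_conv(3L, mid, out)
  )
  names(p) <- paste0(prefix, ".", names(p))
  p
}

ublock_fw <- function(params, prefix, x, training) {
  P <- function(nm) params[[paste0(prefix, ".", nm)]]
  d <- dim(x)
  if (d[1] %% 4L || d[2] %% 4L) {
    stop("U-Block input spatial dimensions must be divisible by 4, got ",
         d[1], "x", d[2], call. = FALSE)
  }
  c1 <- conv_fw(P("e1a"), x)
  c2 <- conv_fw(P("e1b"), c1$y)
  pl1 <- nn_maxpool_fw(c2$y, dim(c2$y))
  c3 <- conv_fw(P("e2a"), pl1$out)
  c4 <- conv_fw(P("e2b"), c3$y)
  pl2 <- nn_maxpool_fw(c4$y, dim(c4$y))
  up1 <- nn_upsample_fw(pl2$out, dim(pl2$out))
  k1 <- cat_ch(up1, c4$y)
  c5 <- conv_fw(P("d1a"), k1)
  c6 <- conv_fw(P("d1b"), c5$y)
  up2 <- nn_upsample_fw(c6$y, dim(c6$y))
  k2 <- cat_ch(up2, c2$y)
  c7 <- conv_fw(P("d2a"), k2)
  c8 <- conv_fw(P("d2b"), c7$y)
  y <- c8$y + adapt_ch(x, dim(c8$y)[3])
  cache <- NULL
  if (training) {
    cache <- list(
      c1 = c1$cache, c2 = c2$cache, c3 = c3$cache, c4 = c4$cache,
      c5 = c5$cache, c6 = c6$cache, c7 = c7$cache, c8 = c8$cache,
      idx1 = pl1$idx, idx2 = pl2$idx,
      dim_c2 = dim(c2$y), dim_c4 = dim(c4$y),
      dim_p2 = dim(pl2$out), dim_c6 = dim(c6$y),
      in_ch = d[3]
    )
  }
  list(y = y, cache = cache)
}

ublock_bw <- function(params, prefix, cache, gy, acc) {
  P <- function(nm) params[[paste0(prefix, ".", nm)]]
  N <- function(nm) paste0(prefix, ".", nm)
  gx_res <- adapt_ch_bw(gy, cache$in_ch)
  r <- conv_bw(P("d2b"), cache$c8, gy); acc_add(acc, N("d2b"), r)
  r <- conv_bw(P("d2a"), cache$c7, r$gx); acc_add(acc, N("d2a"), r)
  sp <- split_ch(r$gx, cache$dim_c6[3])
  g_c6 <- nn_upsample_bw(sp$a, cache$dim_c6)
  g_skip_c2 <- sp$b
  r <- conv_bw(P("d1b"), cache$c6, g_c6); acc_add(acc, N("d1b"), r)
  r <- conv_bw(P("d1a"), cache$c5, r$gx); acc_add(acc, N("d1a"), r)
  sp <- split_ch(r$gx, cache$dim_p2[3])
  g_p2 <- nn_upsample_bw(sp$a, cache$dim_p2)
  g_skip_c4 <- sp$b
  g_c4 <- nn_maxpool_bw(g_p2, cache$idx2, cache$dim_c4) + g_skip_c4
  r <- conv_bw(P("e2b"), cache$c4, g_c4); acc_add(acc, N("e2b"), r)
  r <- conv_bw(P("e2a"), cache$c3, r$gx); acc_add(acc, N("e2a"), r)
  g_c2 <- nn_maxpool_bw(r$gx, cache$idx1, cache$dim_c2) + g_skip_c2
  r <- conv_bw(P("e1b"), cache$c2, g_c2); acc_add(acc, N("e1b"), r)
  r <- conv_bw(P("e1a"), cache$c1, r$gx); acc_add(acc, N("e1a"), r)
  r$gx + gx_res
}

# ---- M-Block: n stacked 3x3 convolutions at constant resolution. ----

mblock_init <- function(prefix, in_ch, filters, out, n) {
  p <- vector("list", n)
  nm <- sprintf("c%d", seq_len(n))
  for (i in seq_len(n)) {
    p[[i]] <- init_conv(3L,
                        if (i == 1L) in_ch else filters,
                        if (i == n) out else filters)
  }
  names(p) <- paste0(prefix, ".", nm)
  p
}

mblock_fw <- function(params, prefix, x, n, training) {
  caches <- if (training) vector("list", n)
  h <- x
  for (i in seq_len(n)) {
    r <- conv_fw(params[[sprintf("%s.c%d", prefix, i)]], h)
    h <- r$y
    if (training) caches[[i]] <- r$cache
  }
  list(y = h, cache = caches)
}

mblock_bw <- function(params, prefix, cache, gy, acc) {
  n <- length(cache)
  for (i in rev(seq_len(n))) {
    nm <- sprintf("%s.c%d", prefix, i)
    r <- conv_bw(params[[nm]], cache[[i]], gy)
    acc_add(acc, nm, r)
    gy <- r$gx
  }
  gy
}

# ---- Model builders ----

#' Build the deep correction network
#'
#' Instantiates the full graph: U-Block 1, concatenation with the input,
#' M-Block, concatenation with its input, U-Block 2, then the BN -> 1x1
#' convolution -> 3x3 convolution head (the only convolution without a ReLU
#' is the final one). Building performs a structural audit and refuses a
#' graph whose convolution count disagrees with the configuration.
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed for weight initialization.
#' @return A model object of class `cc_model`.
#' @export
build_tococonet <- function(cfg = network_config(), seed = 1) {
  stopifnot(inherits(cfg, "network_config"))
  params <- with_seed(seed, {
    mid <- cfg$ublock_mid_filters
    uout <- cfg$ublock_out_channels
    c1_ch <- uout + 3L
    c2_ch <- cfg$mblock_out_channels + c1_ch
    c(
      ublock_init("u1", 3L, mid, uout),
      mblock_init("m", c1_ch, cfg$mblock_filters, cfg$mblock_out_channels,
                  cfg$mblock_conv_layers),
      ublock_init("u2", c2_ch, mid, uout),
      list(
        head.bn = init_bn(uout),
        head.conv1 = init_conv(1L, uout, uout),
        head.conv3 = init_conv(3L, uout, 3L)
      )
    )
  })
  ops <- rbind(
    op_table_ublock("u1"), data.frame(op = "concat", name = "fuse1"),
    data.frame(op = "conv", name = names(params)[grep("^m\\.", names(params))]),
    data.frame(op = "concat", name = "fuse2"),
    op_table_ublock("u2"),
    data.frame(op = c("bn", "conv", "conv"),
               name = c("head.bn", "head.conv1", "head.conv3"))
  )
  model <- structure(
    list(type = "tococonet", config = cfg, params = params,
         bn_state = list(head.bn = list(mean = rep(0, cfg$ublock_out_channels),
                                        var = rep(1, cfg$ublock_out_channels))),
         ops = ops),
    class = "cc_model"
  )
  model$fingerprint <- model_fingerprint(model)
  found <- sum(ops$op == "conv")
  if (found != cfg$total_conv_layers) {
    stop("structural audit failed: graph has ", found,
         " convolutional layers, configuration expects ",
         cfg$total_conv_layers, call. = FALSE)
  }
  model
}

op_table_ublock <- function(prefix) {
  data.frame(
    op = c("conv", "conv", "pool", "conv", "conv", "pool",
           "upsample", "concat", "conv", "conv", "upsample", "concat",
           "conv", "conv", "residual"),
    name = paste0(prefix, ".", c("e1a", "e1b", "pool1", "e2a", "e2b", "pool2",
                                 "up1", "skip1", "d1a", "d1b", "up2", "skip2",
                                 "d2a", "d2b", "res"))
  )
}

#' Build the shallow baseline network
#'
#' Five same-padded 3x3 convolutions (input layer, nonlinear transformation
#' layers, linear output layer), no pooling, no batch normalization. The
#' three scalar adjustment parameters are broadcast as constant extra input
#' channels; at the neutral setting (0, 0, 0) they contribute nothing.
#'
#' @param cfg A [dccn_config()].
#' @param seed Integer seed for weight initialization.
#' @return A model object of class `cc_model`.
#' @export
build_dccn <- function(cfg = dccn_config(), seed = 1) {
  stopifnot(inherits(cfg, "dccn_config"))
  n <- cfg$conv_layers
  params <- with_seed(seed, {
    p <- vector("list", n)
    for (i in seq_len(n)) {
      p[[i]] <- init_conv(3L,
                          if (i == 1L) 3L + cfg$adjustment_params else cfg$filters,
                          if (i == n) 3L else cfg$filters)
    }
    names(p) <- sprintf("conv%d", seq_len(n))
    p
  })
  ops <- data.frame(op = "conv", name = names(params))
  model <- structure(
    list(type = "dccn", config = cfg, params = params, bn_state = list(),
         ops = ops),
    class = "cc_model"
  )
  model$fingerprint <- model_fingerprint(model)
  if (nrow(ops) != cfg$conv_layers) {
    stop("structural audit failed: graph has ", nrow(ops),
         " convolutional layers, configuration expects ", cfg$conv_layers,
         call. = FALSE)
  }
  model
}

model_fingerprint <- function(model) {
  parts <- vapply(names(model$params), function(nm) {
    p <- model$params[[nm]]
    if (!is.null(p$W)) {
      sprintf("%s:conv%dx%d[%dx%d]", nm, p$k, p$k, nrow(p$W), ncol(p$W))
    } else {
      sprintf("%s:bn[%d]", nm, p$ch)
    }
  }, character(1))
  paste(model$type, paste(parts, collapse = ";"), sep = "|")
}

#' Structural audit of a built model
#'
#' Counts the operations in the instantiated graph: convolutional layers,
#' pooling, upsampling, batch-normalization and concatenation nodes.
#'
#' @param model A `cc_model`.
#' @return A named list of counts.
#' @export
audit_network <- function(model) {
  stopifnot(inherits(model, "cc_model"))
  tab <- table(model$ops$op)
  get0 <- function(nm) if (nm %in% names(tab)) as.integer(tab[[nm]]) else 0L
  list(
    conv_layers = get0("conv"),
    pool_ops = get0("pool"),
    upsample_ops = get0("upsample"),
    bn_layers = get0("bn"),
    concat_ops = get0("concat"),
    residual_ops = get0("residual")
  )
}

#' @export
print.cc_model <- function(x, ...) {
  a <- audit_network(x)
  cat(sprintf("<cc_model %s: %d conv | %d pool | %d upsample | %d bn>\n",
              x$type, a$conv_layers, a$pool_ops, a$upsample_ops, a$bn_layers))
  invisible(x)
}

# ---- Forward / backward dispatch ----

toco_fw <- function(model, x, training) {
  params <- model$params
  n <- model$config$mblock_conv_layers
  u1 <- ublock_fw(params, "u1", x, training)
  c1 <- cat_ch(u1$y, x)
  m <- mblock_fw(params, "m", c1, n, training)
  c2 <- cat_ch(m$y, c1)
  u2 <- ublock_fw(params, "u2", c2, training)
  bn <- bn_fw(params$head.bn, model$bn_state$head.bn, u2$y, training)
  h1 <- conv_fw(params$head.conv1, bn$y)
  out <- conv_fw(params$head.conv3, h1$y, act = FALSE)
  caches <- NULL
  if (training) {
    caches <- list(u1 = u1$cache, m = m$cache, u2 = u2$cache, bn = bn$cache,
                   h1 = h1$cache, out = out$cache,
                   c_u1 = dim(u1$y)[3], c_m = dim(m$y)[3])
  }
  list(y = out$y, caches = caches, bn_state = list(head.bn = bn$state))
}

toco_bw <- function(model, caches, gy) {
  params <- model$params
  acc <- new.env(parent = emptyenv())
  acc$g <- list()
  r <- conv_bw(params$head.conv3, caches$out, gy); acc_add(acc, "head.conv3", r)
  r <- conv_bw(params$head.conv1, caches$h1, r$gx); acc_add(acc, "head.conv1", r)
  r <- bn_bw(params$head.bn, caches$bn, r$gx); acc_add(acc, "head.bn", r)
  g_c2 <- ublock_bw(params, "u2", caches$u2, r$gx, acc)
  sp <- split_ch(g_c2, caches$c_m)
  g_c1 <- sp$b
  g_c1 <- g_c1 + mblock_bw(params, "m", caches$m, sp$a, acc)
  sp <- split_ch(g_c1, caches$c_u1)
  gx <- sp$b
  gx <- gx + ublock_bw(params, "u1", caches$u1, sp$a, acc)
  acc$g
}

dccn_fw <- function(model, x, training, adjustment = c(0, 0, 0)) {
  d <- dim(x)
  adj <- array(rep(adjustment, each = d[1] * d[2]), c(d[1], d[2], 3L, d[4]))
  h <- cat_ch(x, adj)
  n <- model$config$conv_layers
  caches <- if (training) vector("list", n)
  for (i in seq_len(n)) {
    r <- conv_fw(model$params[[sprintf("conv%d", i)]], h, act = i < n)
    h <- r$y
    if (training) caches[[i]] <- r$cache
  }
  list(y = h, caches = caches, bn_state = model$bn_state)
}

dccn_bw <- function(model, caches, gy) {
  acc <- new.env(parent = emptyenv())
  acc$g <- list()
  for (i in rev(seq_along(caches))) {
    nm <- sprintf("conv%d", i)
    r <- conv_bw(model$params[[nm]], caches[[i]], gy)
    acc_add(acc, nm, r)
    gy <- r$gx
  }
  acc$g
}

#' Run a model forward
#'
#' @param model A `cc_model`.
#' @param x Input activations, an `(H, W, 3, N)` array in `[0, 1]`.
#' @param training Retain caches and use batch statistics for BN?
#' @param adjustment Three scalar color-adjustment inputs (baseline network
#'   only; `c(0, 0, 0)` is the neutral setting).
#' @return A list with the output `y`, `caches` (when training) and the
#'   updated `bn_state`.
#' @export
model_forward <- function(model, x, training = FALSE, adjustment = c(0, 0, 0)) {
  stopifnot(inherits(model, "cc_model"))
  switch(model$type,
    tococonet = toco_fw(model, x, training),
    dccn = dccn_fw(model, x, training, adjustment),
    stop("unknown model type: ", model$type, call. = FALSE)
  )
}

#' @param caches Caches returned by a training-mode forward pass.
#' @param gy Gradient of the loss with respect to the output.
#' @rdname model_forward
#' @export
model_backward <- function(model, caches, gy) {
  switch(model$type,
    tococonet = toco_bw(model, caches, gy),
    dccn = dccn_bw(model, caches, gy),
    stop("unknown model type: ", model$type, call. = FALSE)
  )
}

# ---- Whole-image inference ----

#' Correct an image with a trained network
#'
#' Normalizes to `[0, 1]`, reflect-pads the image to side lengths divisible
#' by 4 if needed, runs the network in evaluation mode, crops back, clamps
#' to `[0, 1]` and quantizes to 8-bit levels.
#'
#' @param model A `cc_model`.
#' @param img An [rgb_image].
#' @param adjustment Adjustment scalars for the baseline network.
#' @return The corrected [rgb_image].
#' @export
correct_image <- function(model, img, adjustment = c(0, 0, 0)) {
  stopifnot(inherits(model, "cc_model"))
  finite <- all(vapply(model$params, function(p) {
    all(vapply(p[c("W", "b", "gamma", "beta")], function(v) {
      is.null(v) || all(is.finite(v))
    }, logical(1)))
  }, logical(1)))
  if (!finite) stop("model parameters contain non-finite values", call. = FALSE)
  img <- as_rgb_image(img)
  d <- dim(img)
  ph <- (4 - d[1] %% 4) %% 4
  pw <- (4 - d[2] %% 4) %% 4
  x <- unclass(img) / 255
  if (ph > 0 || pw > 0) x <- reflect_pad(x, ph, pw)
  dim(x) <- c(dim(x), 1L)
  y <- model_forward(model, x, training = FALSE, adjustment = adjustment)$y
  y <- y[seq_len(d[1]), seq_len(d[2]), , 1, drop = FALSE]
  dim(y) <- d
  y[y < 0] <- 0
  y[y > 1] <- 1
  quantize_image(y * 255)
}

reflect_pad <- function(x, ph, pw) {
  d <- dim(x)
  ri <- c(seq_len(d[1]), d[1] - seq_len(ph))
  ci <- c(seq_len(d[2]), d[2] - seq_len(pw))
  x[ri, ci, , drop = FALSE]
}

# ---- Checkpoints ----

#' Save and load model checkpoints
#'
#' A checkpoint is a single-file archive of the parameters, configuration,
#' BN running statistics and an architecture fingerprint (layer list with
#' shapes). Loading verifies the fingerprint against the stored parameters
#' and refuses a corrupted or mismatched file.
#'
#' @param model A `cc_model`.
#' @param path Checkpoint file path.
#' @return `load_model()` returns the restored `cc_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cc_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  model <- structure(obj, class = "cc_model")
  if (!identical(model$fingerprint, model_fingerprint(model))) {
    stop("checkpoint fingerprint mismatch: file does not match its declared ",
         "architecture", call. = FALSE)
  }
  model
}
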
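# Layer primitives for the correction networks. Activations flow as
# (H, W, C, N) double arrays in [0, 1]; every primitive has an explicit
# forward (returning a cache) and backward (returning input and parameter
# gradients), wired together by the block functions in nn-model.R.

init_conv <- function(k, in_ch, out_ch) {
  # He-normal fan-in initialization, appropriate for ReLU stacks.
  fan_in <- k * k * in_ch
  list(
    W = matrix(stats::rnorm(fan_in * out_ch, sd = sqrt(2 / fan_in)), fan_in, out_ch),
    b = numeric(out_ch),
    k = k, in_ch = in_ch, out_ch = out_ch
  )
}

conv_fw <- function(p, x, act = TRUE) {
  y <- nn_conv_fw(x, dim(x), p$W, p$b, p$k)
  cache <- list(x = x, mask = NULL)
  if (act) {
    mask <- y > 0
    y <- y * mask
    cache$mask <- mask
  }
  list(y = y, cache = cache)
}

conv_bw <- function(p, cache, gy) {
  if (!is.null(cache$mask)) gy <- gy * cache$mask
  r <- nn_conv_bw(cache$x, dim(cache$x), p$W, p$k, gy)
  list(gx = r$gx, W = r$gW, b = r$gb)
}

# Channel concatenation (a first, then b).
cat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_ch <- function(g, c_first) {
  ctot <- dim(g)[3]
  list(
    a = g[, , seq_len(c_first), , drop = FALSE],
    b = g[, , (c_first + 1):ctot, , drop = FALSE]
  )
}

# Parameter-free channel adaptation for residual connections: zero-pad when
# the block widens, keep the leading channels when it narrows.
adapt_ch <- function(x, out_ch) {
  in_ch <- dim(x)[3]
  if (in_ch == out_ch) return(x)
  if (in_ch < out_ch) {
    d <- dim(x)
    out <- array(0, c(d[1], d[2], out_ch, d[4]))
    out[, , seq_len(in_ch), ] <- x
    out
  } else {
    x[, , seq_len(out_ch), , drop = FALSE]
  }
}

adapt_ch_bw <- function(g, in_ch) {
  out_ch <- dim(g)[3]
  if (in_ch == out_ch) return(g)
  if (in_ch < out_ch) {
    g[, , seq_len(in_ch), , drop = FALSE]
  } else {
    d <- dim(g)
    out <- array(0, c(d[1], d[2], in_ch, d[4]))
    out[, , seq_len(out_ch), ] <- g
    out
  }
}

init_bn <- function(ch) {
  list(gamma = rep(1, ch), beta = rep(0, ch), ch = ch)
}

# Batch normalization over (H, W, N) per channel; biased variance, eps 1e-5,
# running statistics with momentum 0.1 for evaluation mode. Channels are
# moved to the trailing axis once so all per-channel statistics vectorize.
bn_to_mat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
}

bn_from_mat <- function(m, d) {
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

bn_fw <- function(p, state, x, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  xm <- bn_to_mat(x)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm * xm) - mu * mu
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  inv_std <- 1 / sqrt(v + eps)
  xh <- (xm - rep(mu, each = nrow(xm))) * rep(inv_std, each = nrow(xm))
  ym <- xh * rep(p$gamma, each = nrow(xm)) + rep(p$beta, each = nrow(xm))
  list(y = bn_from_mat(ym, d),
       cache = list(xhat = if (training) xh else NULL, inv_std = inv_std,
                    d = d),
       state = state)
}

bn_bw <- function(p, cache, gy) {
  d <- cache$d
  gym <- bn_to_mat(gy)
  xh <- cache$xhat
  m <- nrow(gym)
  ggamma <- colSums(gym * xh)
  gbeta <- colSums(gym)
  dxh <- gym * rep(p$gamma, each = m)
  s1 <- colSums(dxh)
  s2 <- colSums(dxh * xh)
  gxm <- rep(cache$inv_std / m, each = m) *
    (m * dxh - rep(s1, each = m) - xh * rep(s2, each = m))
  list(gx = bn_from_mat(gxm, d), gamma = ggamma, beta = gbeta)
}

# Accumulate parameter gradients (everything but gx) into an environment.
acc_add <- function(acc, name, grads) {
  g <- grads[setdiff(names(grads), "gx")]
  if (is.null(acc$g[[name]])) {
    acc$g[[name]] <- g
  } else {
    for (f in names(g)) acc$g[[name]][[f]] <- acc$g[[name]][[f]] + g[[f]]
  }
  invisible(NULL)
}
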
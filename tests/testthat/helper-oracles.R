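# Independent scalar-loop oracles for the metric formulas. Deliberately
# written element by element, straight from the defining equations, so they
# share no code with the vectorized implementations they check.

rand_img <- function(h = 16, w = 20) {
  rgb_image(array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3)))
}

uniform_img <- function(color, h = 12, w = 12) {
  rgb_image(array(rep(color, each = h * w), c(h, w, 3)))
}

# One RGB triple (0-255) -> L*, a*, b* via the textbook sRGB/D65 formulas.
oracle_lab <- function(rgb) {
  lin <- vapply(rgb / 255, function(u) {
    if (u <= 0.04045) u / 12.92 else ((u + 0.055) / 1.055)^2.4
  }, numeric(1))
  M <- rbind(c(0.4124564, 0.3575761, 0.1804375),
             c(0.2126729, 0.7151522, 0.0721750),
             c(0.0193339, 0.1191920, 0.9503041))
  xyz <- as.numeric(M %*% lin) / c(0.95047, 1, 1.08883)
  f <- vapply(xyz, function(t) {
    if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29
  }, numeric(1))
  c(116 * f[2] - 16, 500 * (f[1] - f[2]), 200 * (f[2] - f[3]))
}

oracle_delta_e_values <- function(a, b) {
  d <- dim(a)
  out <- numeric(d[1] * d[2])
  i <- 0L
  for (cc in seq_len(d[2])) {
    for (rr in seq_len(d[1])) {
      i <- i + 1L
      la <- oracle_lab(c(a[rr, cc, 1], a[rr, cc, 2], a[rr, cc, 3]))
      lb <- oracle_lab(c(b[rr, cc, 1], b[rr, cc, 2], b[rr, cc, 3]))
      out[i] <- sqrt(sum((la - lb)^2))
    }
  }
  out
}

oracle_mae <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + abs(a[i] - b[i])
  s / length(a) / 255
}

oracle_rmse <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  sqrt(s / length(a)) / 255
}

oracle_psnr <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  mse <- s / length(a)
  10 * log10(255^2 / mse)
}

# Windowed SSIM by explicit loops over every 11x11 window position.
oracle_ssim <- function(a, b) {
  g <- exp(-((-5:5)^2) / (2 * 1.5^2))
  w <- outer(g, g)
  w <- w / sum(w)
  c1 <- (0.01 * 255)^2
  c2 <- (0.03 * 255)^2
  d <- dim(a)
  ch_means <- numeric(3)
  for (ch in 1:3) {
    x <- a[, , ch]
    y <- b[, , ch]
    vals <- c()
    for (i in seq_len(d[1] - 10)) {
      for (j in seq_len(d[2] - 10)) {
        wx <- x[i:(i + 10), j:(j + 10)]
        wy <- y[i:(i + 10), j:(j + 10)]
        mx <- sum(w * wx); my <- sum(w * wy)
        vx <- sum(w * wx^2) - mx^2
        vy <- sum(w * wy^2) - my^2
        vxy <- sum(w * wx * wy) - mx * my
        vals <- c(vals, ((2 * mx * my + c1) * (2 * vxy + c2)) /
                    ((mx^2 + my^2 + c1) * (vx + vy + c2)))
      }
    }
    ch_means[ch] <- mean(vals)
  }
  mean(ch_means)
}

# Relative error between analytic and finite-difference gradients for
# randomly probed parameters of a model.
gradient_probe_error <- function(model, x, target, nprobe = 25, eps = 1e-5) {
  fw <- model_forward(model, x, training = TRUE)
  gy <- 2 * (fw$y - target) / length(target)
  grads <- model_backward(model, fw$caches, gy)
  worst <- 0
  for (probe in seq_len(nprobe)) {
    nm <- sample(names(grads), 1)
    f <- sample(names(grads[[nm]]), 1)
    i <- sample(length(grads[[nm]][[f]]), 1)
    mp <- model; mp$params[[nm]][[f]][i] <- mp$params[[nm]][[f]][i] + eps
    mm <- model; mm$params[[nm]][[f]][i] <- mm$params[[nm]][[f]][i] - eps
    num <- (mse_loss(model_forward(mp, x, training = TRUE)$y, target) -
            mse_loss(model_forward(mm, x, training = TRUE)$y, target)) / (2 * eps)
    ana <- grads[[nm]][[f]][i]
    worst <- max(worst, abs(num - ana) / max(1e-6, abs(num) + abs(ana)))
  }
  worst
}

# A small paired dataset built directly from in-memory patches.
toy_dataset <- function(patches_biased, patches_clean, sources, seed = 1) {
  p <- length(patches_biased)
  sz <- dim(patches_biased[[1]])[1]
  ba <- array(0L, c(sz, sz, 3L, p))
  ca <- array(0L, c(sz, sz, 3L, p))
  for (i in seq_len(p)) {
    ba[, , , i] <- as.integer(patches_biased[[i]])
    ca[, , , i] <- as.integer(patches_clean[[i]])
  }
  info <- split_dataset(data.frame(source = sources), seed = seed)
  patch_dataset(ba, ca, info)
}
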
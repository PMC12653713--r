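#' Synthetic tongue-scene specification
#'
#' Describes one rendered test scene: an anti-aliased reddish ellipse (the
#' tongue body) with a radial lightness gradient, per-pixel speckle texture
#' and optional pale coating patches, on a neutral background. Realism is
#' deliberately minimal — the correction task depends on color statistics,
#' not anatomy — but the gradient pushes some highlight pixels close to
#' saturation so both the clipping and non-clipping paths of channel casts
#' are exercised. Ellipse geometry is drawn from the seed and kept fully
#' inside the canvas.
#'
#' @param canvas_size Square canvas side in pixels (default 640).
#' @param seed Integer seed; everything about the scene derives from it.
#' @param base_color Reddish RGB triple of the tongue body (R must dominate).
#' @param background Neutral background RGB triple.
#' @param gradient_amplitude Relative lightness boost at the ellipse centre.
#' @param noise_amplitude Speckle noise standard deviation in levels.
#' @param coating_prob Probability that pale coating patches are added.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(canvas_size = 640L, seed = 1,
                       base_color = c(180, 90, 95),
                       background = c(170, 170, 170),
                       gradient_amplitude = 0.3,
                       noise_amplitude = 6,
                       coating_prob = 0.5) {
  if (base_color[1] <= base_color[2] || base_color[1] <= base_color[3]) {
    stop("base_color must be reddish (R > G and R > B)", call. = FALSE)
  }
  if (any(c(base_color, background) < 0) || any(c(base_color, background) > 255)) {
    stop("colors must lie in [0, 255]", call. = FALSE)
  }
  n <- as.integer(canvas_size)
  geom <- with_seed(seed, {
    list(
      center = n / 2 * (1 + stats::runif(2, -0.05, 0.05)),
      axes = n * c(stats::runif(1, 0.26, 0.32), stats::runif(1, 0.34, 0.42)),
      rotation = stats::runif(1, -0.2, 0.2)
    )
  })
  ext_x <- sqrt((geom$axes[1] * cos(geom$rotation))^2 +
                (geom$axes[2] * sin(geom$rotation))^2)
  ext_y <- sqrt((geom$axes[1] * sin(geom$rotation))^2 +
                (geom$axes[2] * cos(geom$rotation))^2)
  if (geom$center[1] - ext_x < 0 || geom$center[1] + ext_x > n ||
      geom$center[2] - ext_y < 0 || geom$center[2] + ext_y > n) {
    stop("ellipse does not fit inside the canvas", call. = FALSE)
  }
  structure(
    list(canvas_size = n, seed = seed, base_color = base_color,
         background = background, gradient_amplitude = gradient_amplitude,
         noise_amplitude = noise_amplitude, coating_prob = coating_prob,
         center = geom$center, axes = geom$axes, rotation = geom$rotation),
    class = "scene_spec"
  )
}

#' Render a synthetic tongue image
#'
#' Deterministic for a given spec (same seed, bit-identical image).
#'
#' @param spec A [scene_spec()].
#' @return An [rgb_image] of side `spec$canvas_size`.
#' @export
generate_tongue_image <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  n <- spec$canvas_size
  row <- matrix(seq_len(n), n, n)
  col <- matrix(seq_len(n), n, n, byrow = TRUE)
  xr <- (col - spec$center[1]) * cos(spec$rotation) +
        (row - spec$center[2]) * sin(spec$rotation)
  yr <- -(col - spec$center[1]) * sin(spec$rotation) +
        (row - spec$center[2]) * cos(spec$rotation)
  r <- sqrt((xr / spec$axes[1])^2 + (yr / spec$axes[2])^2)
  edge <- 2 / min(spec$axes)  # ~2 px anti-aliased rim
  alpha <- pmin(1, pmax(0, (1 - r) / edge))
  bright <- 1 + spec$gradient_amplitude * (1 - pmin(r, 1)^2)

  with_seed(child_seed(spec$seed, 1), {
    img <- array(0, c(n, n, 3))
    coat <- coating_mask(spec, xr, yr)
    coat_color <- c(215, 210, 200)
    for (ch in 1:3) {
      tongue <- spec$base_color[ch] * bright +
        stats::rnorm(n * n, sd = spec$noise_amplitude)
      tongue <- tongue * (1 - coat) + coat * coat_color[ch]
      bg <- spec$background[ch] + stats::rnorm(n * n, sd = 2)
      img[, , ch] <- alpha * tongue + (1 - alpha) * bg
    }
    quantize_image(img)
  })
}

# Soft mask (0-1) of pale coating blobs in the upper tongue half; consumes
# RNG even when no coating is drawn, keeping the stream layout stable.
coating_mask <- function(spec, xr, yr) {
  coat <- 0
  has <- stats::runif(1) < spec$coating_prob
  k <- sample(1:3, 1)
  for (i in seq_len(k)) {
    cx <- stats::runif(1, -0.3, 0.3) * spec$axes[1]
    cy <- stats::runif(1, -0.55, -0.1) * spec$axes[2]
    ax <- stats::runif(1, 0.10, 0.22) * spec$axes[1]
    ay <- stats::runif(1, 0.10, 0.22) * spec$axes[2]
    if (has) {
      rk <- sqrt(((xr - cx) / ax)^2 + ((yr - cy) / ay)^2)
      coat <- pmax(coat, 0.6 * pmin(1, pmax(0, (1 - rk) / 0.3)))
    }
  }
  coat
}

#' Generate uniform color blocks
#'
#' Single-color patches drawn from a tongue-plausible distribution: 80% of
#' blocks are truncated-Gaussian around the reddish tongue hue
#' (180, 90, 95), the rest neutral grays. With `chart = TRUE` the 24 nominal
#' colors of the embedded reference chart are returned instead (and `n` must
#' be 24).
#'
#' @param n Number of blocks.
#' @param seed Integer seed.
#' @param size Block side in pixels.
#' @param chart Return the 24-patch reference chart colors?
#' @return A list of uniform [rgb_image] patches.
#' @export
generate_color_blocks <- function(n, seed = 1, size = 32L, chart = FALSE) {
  if (n < 1L) stop("n must be at least 1", call. = FALSE)
  if (chart) {
    ref <- colorchecker_chart()
    if (n != nrow(ref)) {
      stop("chart mode requires n = ", nrow(ref), call. = FALSE)
    }
    cols <- as.matrix(ref[, c("R", "G", "B")])
  } else {
    cols <- with_seed(seed, {
      m <- cbind(stats::rnorm(n, 180, 35), stats::rnorm(n, 90, 30),
                 stats::rnorm(n, 95, 30))
      neutral <- stats::runif(n) < 0.2
      g <- stats::runif(n, 60, 220)
      m[neutral, ] <- cbind(g, g, g)[neutral, ]
      pmin(pmax(m, 0), 255)
    })
  }
  lapply(seq_len(n), function(i) {
    quantize_image(array(rep(cols[i, ], each = size * size), c(size, size, 3)))
  })
}

#' Build a paired benchmark dataset from synthetic scenes
#'
#' Renders `n_images` seeded scenes, applies every requested cast kind to
#' each (canonical severity: adjustment 50 for channel casts, contrast and
#' offset drawn from their simulation ranges for brightness kinds;
#' randomized severity: [sample_random_bias()]), extracts aligned
#' sliding-window patches from the clean and biased versions, and splits
#' 60/30/10 by source image. The manifest records the exact [bias_spec()]
#' parameters per (image, kind) so any biased image can be replayed
#' bit-identically.
#'
#' @param n_images Number of source scenes (at least 3 for split feasibility).
#' @param kinds Character vector of bias kinds (see [bias_kinds()]).
#' @param seed Integer master seed.
#' @param canvas_size Scene side in pixels.
#' @param patch_size,step Patch extraction geometry.
#' @param severity `"canonical"` or `"random"`.
#' @param ratios Train/val/test proportions.
#' @return A [patch_dataset()] with a manifest.
#' @export
make_benchmark_dataset <- function(n_images, kinds = "bluish", seed = 1,
                                   canvas_size = 640L, patch_size = 160L,
                                   step = 80L,
                                   severity = c("canonical", "random"),
                                   ratios = c(0.6, 0.3, 0.1)) {
  severity <- match.arg(severity)
  if (n_images < 3L) stop("need at least 3 source images", call. = FALSE)
  kinds <- vapply(kinds, function(k) match.arg(k, bias_kinds()), character(1))
  biased_list <- list()
  clean_list <- list()
  info <- list()
  manifest <- list()
  for (i in seq_len(n_images)) {
    sp <- scene_spec(canvas_size, seed = child_seed(seed, i))
    clean_img <- generate_tongue_image(sp)
    clean_patches <- extract_patches(clean_img, patch_size, step)
    for (j in seq_along(kinds)) {
      kseed <- child_seed(seed, i * 1000 + j)
      bs <- if (severity == "random") {
        sample_random_bias(kinds[j], kseed)
      } else if (kinds[j] %in% c("lower_brightness", "higher_brightness")) {
        with_seed(kseed, bias_spec(kinds[j], contrast = stats::runif(1, 0.8, 1),
                                   brightness_offset = stats::runif(1, 0, 30),
                                   seed = kseed))
      } else {
        bias_spec(kinds[j], adjustment = 50, seed = kseed)
      }
      biased_img <- apply_bias(clean_img, bs)
      biased_patches <- extract_patches(biased_img, patch_size, step)
      np <- length(clean_patches)
      biased_list <- c(biased_list, biased_patches)
      clean_list <- c(clean_list, clean_patches)
      info[[length(info) + 1L]] <- data.frame(
        source = rep(i, np), kind = rep(kinds[j], np)
      )
      manifest[[length(manifest) + 1L]] <- data.frame(
        source = i, kind = bs$kind, contrast = bs$contrast,
        brightness_offset = bs$brightness_offset, adjustment = bs$adjustment,
        seed = bs$seed
      )
    }
  }
  info <- do.call(rbind, info)
  info <- split_dataset(info, ratios, seed = child_seed(seed, 0))
  p <- length(biased_list)
  ba <- array(0L, c(patch_size, patch_size, 3L, p))
  ca <- array(0L, c(patch_size, patch_size, 3L, p))
  for (i in seq_len(p)) {
    ba[, , , i] <- as.integer(biased_list[[i]])
    ca[, , , i] <- as.integer(clean_list[[i]])
  }
  patch_dataset(ba, ca, info, manifest = do.call(rbind, manifest))
}

#' Rebuild the bias specification of one manifest row
#'
#' @param manifest The manifest data frame of a benchmark dataset.
#' @param row Row index.
#' @return The [bias_spec()] recorded in that row.
#' @export
manifest_bias_spec <- function(manifest, row) {
  m <- manifest[row, ]
  bias_spec(m$kind, contrast = m$contrast,
            brightness_offset = m$brightness_offset,
            adjustment = m$adjustment, seed = m$seed)
}
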
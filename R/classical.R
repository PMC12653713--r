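#' Gray-world correction
#'
#' Under the gray-world assumption the average color of a scene is
#' achromatic, so the channel means of an unbiased image should agree. Each
#' channel is rescaled by `K / channel_mean` with
#' `K = (R_avg + G_avg + B_avg) / 3`, then quantized with clamping.
#'
#' @param img An [rgb_image].
#' @return A corrected [rgb_image].
#' @export
gray_world <- function(img) {
  img <- as_rgb_image(img)
  mu <- apply(unclass(img), 3, mean)
  if (any(mu == 0)) {
    stop("gray world is undefined when a channel mean is zero", call. = FALSE)
  }
  scale_channels(img, rep(mean(mu), 3), mu)
}

#' Perfect-reflection correction
#'
#' Assumes the brightest scene point (the pixel maximizing R + G + B; ties
#' broken by first occurrence in column-major order) is a white reflector.
#' Each channel is rescaled so that this pixel maps to (255, 255, 255).
#'
#' @param img An [rgb_image].
#' @return A corrected [rgb_image].
#' @export
perfect_reflection <- function(img) {
  img <- as_rgb_image(img)
  x <- unclass(img)
  s <- x[, , 1] + x[, , 2] + x[, , 3]
  i <- which.max(s)
  wp <- c(x[, , 1][i], x[, , 2][i], x[, , 3][i])
  if (any(wp == 0)) {
    stop("brightest pixel has a zero channel; perfect reflection is undefined",
         call. = FALSE)
  }
  scale_channels(img, c(255, 255, 255), wp)
}

#' Standard-deviation-weighted gray world (SDW)
#'
#' A combination of the gray-world and perfect-reflection ideas: the image is
#' tiled into 16x16 blocks and the channel means entering the gray-world
#' scaling are replaced by block means weighted by each block's spatial
#' standard deviation (per-channel, averaged over channels, normalized to
#' sum to 1 across blocks). Flat
#' single-color regions get low weight and no longer dominate the mean. If
#' every block has zero variance the method falls back to plain gray world.
#'
#' @param img An [rgb_image] of at least 16x16 pixels.
#' @param block_size Side of the square blocks (default 16).
#' @return A corrected [rgb_image].
#' @export
sdw_correct <- function(img, block_size = 16L) {
  img <- as_rgb_image(img)
  d <- dim(img)
  if (d[1] < block_size || d[2] < block_size) {
    stop("sdw_correct requires an image of at least ", block_size, "x",
         block_size, " pixels", call. = FALSE)
  }
  x <- unclass(img)
  rows <- block_index(d[1], block_size)
  cols <- block_index(d[2], block_size)
  nb <- length(rows) * length(cols)
  sds <- numeric(nb)
  bm <- matrix(0, nb, 3)
  b <- 0L
  for (rr in rows) {
    for (cc in cols) {
      b <- b + 1L
      blk <- x[rr, cc, , drop = FALSE]
      # spatial variation only: per-channel sd, averaged, so a flat but
      # saturated color block still gets zero weight
      sds[b] <- mean(apply(blk, 3, stats::sd))
      bm[b, ] <- apply(blk, 3, mean)
    }
  }
  if (sum(sds) == 0) return(gray_world(img))
  w <- sds / sum(sds)
  mu <- colSums(bm * w)
  if (any(mu == 0)) {
    stop("weighted channel mean of zero; sdw correction is undefined", call. = FALSE)
  }
  scale_channels(img, rep(mean(mu), 3), mu)
}

block_index <- function(n, size) {
  starts <- seq.int(1L, n, by = size)
  lapply(starts, function(s) s:min(s + size - 1L, n))
}

# Scale each channel by num[ch] / den[ch]; multiplying before dividing keeps
# exact halves (e.g. 100 * 255 / 200) exact for the half-away rounding rule.
scale_channels <- function(img, num, den) {
  x <- unclass(img)
  for (ch in 1:3) x[, , ch] <- x[, , ch] * num[ch] / den[ch]
  quantize_image(x)
}

#' Nominal sRGB values of the 24-patch reference chart
#'
#' The widely published nominal sRGB coordinates of the standard 24-patch
#' color rendition chart used for chart-based calibration, embedded so that
#' polynomial correction is self-contained. Users with a measured chart can
#' supply their own values via [read_chart_csv()].
#'
#' @return A data frame with columns `name`, `R`, `G`, `B` (24 rows).
#' @export
colorchecker_chart <- function() {
  data.frame(
    name = c("dark skin", "light skin", "blue sky", "foliage", "blue flower",
             "bluish green", "orange", "purplish blue", "moderate red",
             "purple", "yellow green", "orange yellow", "blue", "green",
             "red", "yellow", "magenta", "cyan", "white 9.5", "neutral 8",
             "neutral 6.5", "neutral 5", "neutral 3.5", "black 2"),
    R = c(115, 194, 98, 87, 133, 103, 214, 80, 193, 94, 157, 224,
          56, 70, 175, 231, 187, 8, 243, 200, 160, 122, 85, 52),
    G = c(82, 150, 122, 108, 128, 189, 126, 91, 90, 60, 188, 163,
          61, 148, 54, 199, 86, 133, 243, 200, 160, 122, 85, 52),
    B = c(68, 130, 157, 67, 177, 170, 44, 166, 99, 108, 64, 46,
          150, 73, 60, 31, 149, 161, 242, 200, 160, 121, 85, 52)
  )
}

#' @param path CSV file with columns `name,R,G,B`.
#' @rdname colorchecker_chart
#' @export
read_chart_csv <- function(path) {
  chart <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "R", "G", "B")
  if (!all(need %in% names(chart))) {
    stop("chart CSV must have columns name,R,G,B", call. = FALSE)
  }
  if (any(chart$R < 0 | chart$R > 255 | chart$G < 0 | chart$G > 255 |
          chart$B < 0 | chart$B > 255)) {
    stop("chart values must lie in [0, 255]", call. = FALSE)
  }
  chart[, need]
}

# Second-order polynomial expansion of n x 3 colors normalized to [0, 1].
# The linear terms come first so the identity map lies in the model class.
poly_expand <- function(m, terms) {
  r <- m[, 1]; g <- m[, 2]; b <- m[, 3]
  cols <- list(R = r, G = g, B = b, R2 = r * r, G2 = g * g, B2 = b * b,
               RG = r * g, RB = r * b, GB = g * b, RGB = r * g * b,
               const = rep(1, length(r)))
  do.call(cbind, cols[terms])
}

default_poly_terms <- function() {
  c("R", "G", "B", "R2", "G2", "B2", "RG", "RB", "GB", "RGB", "const")
}

#' Fit a polynomial color-correction map from chart patches
#'
#' Least-squares fit of a linear map from a polynomial expansion of observed
#' (cast-affected) patch colors to the reference patch colors. The default
#' expansion is the 11-term second-order set
#' `{R, G, B, R^2, G^2, B^2, RG, RB, GB, RGB, 1}`; colors are normalized to
#' `[0, 1]` internally for conditioning.
#'
#' @param observed Data frame or matrix of observed patch colors: columns
#'   `R`, `G`, `B` (levels 0-255), one row per patch.
#' @param reference Reference patch colors in the same format and order
#'   (default the embedded 24-patch chart, [colorchecker_chart()]).
#' @param terms Character vector of expansion terms (subset of the default).
#' @return A list of class `polynomial_map` with the `terms` used and the
#'   fitted `coefficients` (one column per output channel).
#' @export
fit_polynomial_map <- function(observed, reference = colorchecker_chart(),
                               terms = default_poly_terms()) {
  obs <- chart_colors(observed)
  ref <- chart_colors(reference)
  if (nrow(obs) != nrow(ref)) {
    stop("observed and reference must have the same number of patches", call. = FALSE)
  }
  terms <- match.arg(terms, default_poly_terms(), several.ok = TRUE)
  if (!all(c("R", "G", "B") %in% terms)) {
    stop("the expansion must include the three linear terms", call. = FALSE)
  }
  if (nrow(obs) < length(terms)) {
    stop("need at least as many patches (", nrow(obs), ") as expansion terms (",
         length(terms), ")", call. = FALSE)
  }
  V <- poly_expand(obs / 255, terms)
  qrV <- qr(V)
  if (qrV$rank < ncol(V)) {
    stop("rank-deficient patch design: the observed colors do not span the ",
         "polynomial expansion; use fewer terms or more varied patches",
         call. = FALSE)
  }
  coef <- qr.coef(qrV, ref / 255)
  structure(list(terms = terms, coefficients = coef), class = "polynomial_map")
}

chart_colors <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("R", "G", "B")])
  if (!is.matrix(x) || ncol(x) != 3L) {
    stop("patch colors must be an n x 3 matrix or a data frame with R,G,B",
         call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

#' @export
print.polynomial_map <- function(x, ...) {
  cat("<polynomial_map:", length(x$terms), "terms ->", ncol(x$coefficients),
      "channels>\n")
  invisible(x)
}

#' Apply a fitted polynomial map to an image
#'
#' Expands every pixel with the map's polynomial terms, applies the fitted
#' linear map, and quantizes with clamping to `[0, 255]`.
#'
#' @param map A `polynomial_map` from [fit_polynomial_map()].
#' @param img An [rgb_image].
#' @return A corrected [rgb_image].
#' @export
apply_polynomial_map <- function(map, img) {
  if (!inherits(map, "polynomial_map")) stop("map must be a polynomial_map", call. = FALSE)
  img <- as_rgb_image(img)
  d <- dim(img)
  m <- matrix(as.numeric(img), ncol = 3L) / 255
  out <- poly_expand(m, map$terms) %*% map$coefficients
  quantize_image(array(out * 255, d))
}
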
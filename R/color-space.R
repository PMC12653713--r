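#' Convert between sRGB and CIELAB
#'
#' Standard sRGB -> XYZ (D65 white point) -> CIELAB transform, the color
#' space in which chromatic distance is measured. `rgb_to_lab()` maps 8-bit
#' levels to per-pixel `L*` (0-100), `a*` (green-red) and `b*` (blue-yellow);
#' `lab_to_rgb()` is its inverse and quantizes back to 8-bit levels.
#'
#' @param img An [rgb_image].
#' @return `rgb_to_lab()` returns an `H x W x 3` array of class `lab_image`;
#'   `lab_to_rgb()` returns an [rgb_image].
#' @export
rgb_to_lab <- function(img) {
  img <- as_rgb_image(img)
  d <- dim(img)
  m <- matrix(as.numeric(img), ncol = 3L)
  lab <- srgb_matrix_to_lab(m)
  out <- array(lab, d)
  structure(out, class = c("lab_image", "array"))
}

#' @param lab A `lab_image` (or `H x W x 3` array of L*, a*, b*).
#' @rdname rgb_to_lab
#' @export
lab_to_rgb <- function(lab) {
  d <- dim(lab)
  if (is.null(d) || length(d) != 3L || d[3] != 3L) {
    stop("lab input must be an H x W x 3 array", call. = FALSE)
  }
  m <- matrix(as.numeric(lab), ncol = 3L)
  rgb <- lab_matrix_to_srgb(m)
  quantize_image(array(rgb, d))
}

# D65 reference white (2 degree observer), Y normalized to 1.
.lab_white <- c(X = 0.95047, Y = 1.0, Z = 1.08883)

.rgb2xyz <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)

srgb_matrix_to_lab <- function(m) {
  v <- m / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.rgb2xyz)
  xyz <- sweep(xyz, 2, .lab_white, "/")
  eps <- (6 / 29)^3
  f <- ifelse(xyz > eps, xyz^(1 / 3), xyz / (3 * (6 / 29)^2) + 4 / 29)
  cbind(
    L = 116 * f[, 2] - 16,
    a = 500 * (f[, 1] - f[, 2]),
    b = 200 * (f[, 2] - f[, 3])
  )
}

lab_matrix_to_srgb <- function(m) {
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  finv <- function(t) ifelse(t > 6 / 29, t^3, 3 * (6 / 29)^2 * (t - 4 / 29))
  xyz <- cbind(finv(fx), finv(fy), finv(fz))
  xyz <- sweep(xyz, 2, .lab_white, "*")
  lin <- xyz %*% t(solve(.rgb2xyz))
  lin[lin < 0] <- 0
  v <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
  v * 255
}
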
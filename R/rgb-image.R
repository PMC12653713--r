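#' 8-bit RGB image container
#'
#' The universal currency of the package: a numeric `H x W x 3` array with
#' integer levels in `[0, 255]`, channels ordered R, G, B. All correctors,
#' simulators and metrics consume and return this type.
#'
#' @param x A numeric array of dimension `H x W x 3` with values in
#'   `[0, 255]`. Values are rounded (half away from zero) to integer levels.
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("an rgb_image must be a 3-dimensional array", call. = FALSE)
  }
  d <- dim(x)
  if (d[3] != 3L) {
    stop("an rgb_image must have exactly 3 channels, got ", d[3], call. = FALSE)
  }
  if (d[1] < 1L || d[2] < 1L) stop("image dimensions must be at least 1x1", call. = FALSE)
  if (anyNA(x) || !all(is.finite(x))) stop("image values must be finite", call. = FALSE)
  if (min(x) < 0 || max(x) > 255) {
    stop("image values must lie in [0, 255]", call. = FALSE)
  }
  x <- round_half_away(x)
  structure(x, class = c("rgb_image", "array"))
}

#' @rdname rgb_image
#' @export
is_rgb_image <- function(x) inherits(x, "rgb_image")

#' @rdname rgb_image
#' @export
as_rgb_image <- function(x) {
  if (is_rgb_image(x)) return(x)
  rgb_image(x)
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  mu <- round(apply(x, 3, mean), 1)
  cat(sprintf("<rgb_image %dx%d, channel means R=%.1f G=%.1f B=%.1f>\n",
              d[1], d[2], mu[1], mu[2], mu[3]))
  invisible(x)
}

# Round half away from zero (the quantization rule used throughout; base
# round() would round half to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Clamp + quantize floating point channel values to valid 8-bit levels.
quantize_levels <- function(x) {
  x <- round_half_away(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

# Build an rgb_image from float values, clamping once at the 8-bit boundary.
quantize_image <- function(x) {
  structure(quantize_levels(x), class = c("rgb_image", "array"))
}

#' Read and write 8-bit RGB images
#'
#' PNG is read natively; JPEG requires the optional \pkg{jpeg} package.
#' Images with an alpha channel are rejected: the pipeline is defined on
#' opaque 3-channel pictures.
#'
#' @param path File path ending in `.png`, `.jpg` or `.jpeg`.
#' @return `read_image()` returns an [rgb_image]; `write_image()` returns
#'   `path` invisibly (PNG output only).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        stop("reading JPEG requires the 'jpeg' package", call. = FALSE)
      }
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: '", ext, "' (use PNG or JPEG)", call. = FALSE)
  )
  if (length(dim(raw)) == 2L) {
    raw <- array(raw, c(dim(raw), 3L))  # grayscale promoted to RGB
  }
  if (dim(raw)[3] == 4L) {
    stop("images with an alpha channel are not supported", call. = FALSE)
  }
  rgb_image(raw[, , 1:3, drop = FALSE] * 255)
}

#' @param img An [rgb_image].
#' @rdname read_image
#' @export
write_image <- function(img, path) {
  img <- as_rgb_image(img)
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All seeded generation in the package goes
# through this so that global RNG state is never disturbed.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Stable per-item child seed derived from a base seed (kept below 2^31).
child_seed <- function(seed, i) {
  (as.double(seed) * 48271 + as.double(i) * 16807) %% 2147483647
}
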
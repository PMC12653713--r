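#' Parameterized color-cast specification
#'
#' Describes one color degradation. Brightness kinds rescale and shift all
#' channels (`v * contrast +/- brightness_offset`, computed in floating point
#' and clamped only at the final 8-bit quantization); channel-cast kinds add
#' `adjustment` to one channel with saturation at 255.
#'
#' @param kind One of `"lower_brightness"`, `"higher_brightness"`,
#'   `"reddish"`, `"greenish"`, `"bluish"`.
#' @param contrast Multiplicative factor in `[0.8, 1]` (brightness kinds).
#' @param brightness_offset Additive offset in levels, `[0, 30]` (brightness
#'   kinds).
#' @param adjustment Non-negative additive level for channel casts
#'   (default 50, the canonical training severity).
#' @param seed Optional integer recorded with the spec for provenance.
#' @return A list of class `bias_spec`.
#' @export
bias_spec <- function(kind, contrast = 1, brightness_offset = 0,
                      adjustment = 50, seed = NA_integer_) {
  kind <- match.arg(kind, bias_kinds())
  if (!is.numeric(contrast) || contrast < 0.8 || contrast > 1) {
    stop("contrast must lie in [0.8, 1]", call. = FALSE)
  }
  if (!is.numeric(brightness_offset) || brightness_offset < 0 || brightness_offset > 30) {
    stop("brightness_offset must lie in [0, 30]", call. = FALSE)
  }
  if (!is.numeric(adjustment) || adjustment < 0) {
    stop("adjustment must be non-negative", call. = FALSE)
  }
  structure(
    list(kind = kind, contrast = contrast, brightness_offset = brightness_offset,
         adjustment = adjustment, seed = seed),
    class = "bias_spec"
  )
}

#' @rdname bias_spec
#' @export
bias_kinds <- function() {
  c("lower_brightness", "higher_brightness", "reddish", "greenish", "bluish")
}

#' @export
print.bias_spec <- function(x, ...) {
  if (x$kind %in% c("lower_brightness", "higher_brightness")) {
    cat(sprintf("<bias_spec %s: contrast=%.3f offset=%.2f>\n",
                x$kind, x$contrast, x$brightness_offset))
  } else {
    cat(sprintf("<bias_spec %s: adjustment=%.2f>\n", x$kind, x$adjustment))
  }
  invisible(x)
}

#' Apply a global brightness bias
#'
#' Every channel value `v` becomes `v * contrast - offset` (direction
#' `"lower"`) or `v * contrast + offset` (direction `"higher"`). The math is
#' carried out in floating point without intermediate cropping; values are
#' clamped to `[0, 255]` once, at 8-bit quantization (with `contrast <= 1`
#' and `offset <= 30` the pre-clamp maximum is 285).
#'
#' @param img An [rgb_image].
#' @param contrast Factor in `[0.8, 1]`.
#' @param brightness_offset Offset in levels, `[0, 30]`.
#' @param direction `"lower"` (subtract) or `"higher"` (add).
#' @return A biased [rgb_image].
#' @export
apply_brightness_bias <- function(img, contrast, brightness_offset,
                                  direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  if (contrast < 0.8 || contrast > 1) stop("contrast must lie in [0.8, 1]", call. = FALSE)
  if (brightness_offset < 0 || brightness_offset > 30) {
    stop("brightness_offset must lie in [0, 30]", call. = FALSE)
  }
  img <- as_rgb_image(img)
  s <- if (direction == "lower") -1 else 1
  quantize_image(unclass(img) * contrast + s * brightness_offset)
}

#' Apply a single-channel color cast
#'
#' Adds `adjustment` to every value of one channel, saturating at 255
#' (`min(255, v + adjustment)`); the other channels are untouched.
#'
#' @param img An [rgb_image].
#' @param channel `"R"`, `"G"` or `"B"`.
#' @param adjustment Non-negative level to add.
#' @return A biased [rgb_image].
#' @export
apply_channel_cast <- function(img, channel = c("R", "G", "B"), adjustment) {
  channel <- match.arg(channel)
  if (!is.numeric(adjustment) || adjustment < 0) {
    stop("adjustment must be non-negative", call. = FALSE)
  }
  img <- as_rgb_image(img)
  ch <- match(channel, c("R", "G", "B"))
  out <- unclass(img)
  out[, , ch] <- pmin(255, out[, , ch] + adjustment)
  quantize_image(out)
}

#' Draw a randomized-severity cast specification
#'
#' For brightness kinds, contrast is uniform on `[0.8, 1]` and the offset
#' uniform on `[0, 30]` (the simulation ranges used for training). For
#' channel casts the adjustment is uniform on `[10, 50]`, spanning mild casts
#' up to the canonical severity. Identical `(kind, seed)` always yields the
#' identical spec.
#'
#' @param kind A bias kind, see [bias_kinds()].
#' @param seed Integer seed.
#' @return A [bias_spec].
#' @export
sample_random_bias <- function(kind, seed) {
  kind <- match.arg(kind, bias_kinds())
  with_seed(seed, {
    bias_spec(
      kind = kind,
      contrast = stats::runif(1, 0.8, 1),
      brightness_offset = stats::runif(1, 0, 30),
      adjustment = stats::runif(1, 10, 50),
      seed = seed
    )
  })
}

#' Apply a cast specification to an image
#'
#' Dispatches on the spec's kind: brightness kinds go through
#' [apply_brightness_bias()], and `reddish`/`greenish`/`bluish` add the
#' adjustment to the R/G/B channel respectively via [apply_channel_cast()].
#'
#' @param img An [rgb_image].
#' @param spec A [bias_spec].
#' @return A biased [rgb_image].
#' @export
apply_bias <- function(img, spec) {
  if (!inherits(spec, "bias_spec")) stop("spec must be a bias_spec", call. = FALSE)
  switch(spec$kind,
    lower_brightness = apply_brightness_bias(img, spec$contrast,
                                             spec$brightness_offset, "lower"),
    higher_brightness = apply_brightness_bias(img, spec$contrast,
                                              spec$brightness_offset, "higher"),
    reddish = apply_channel_cast(img, "R", spec$adjustment),
    greenish = apply_channel_cast(img, "G", spec$adjustment),
    bluish = apply_channel_cast(img, "B", spec$adjustment)
  )
}
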
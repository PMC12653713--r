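#' Per-pixel chromatic distance summary
#'
#' Computes the CIE76 color difference `dE = sqrt(dL*^2 + da*^2 + db*^2)`
#' between two images pixel by pixel in CIELAB, and summarizes the
#' distribution over all pixels into five levels: mean, quartiles Q1-Q3
#' (linear interpolation) and maximum.
#'
#' @param a,b [rgb_image]s of identical dimensions.
#' @return A list of class `delta_e_summary` with fields `mean`, `q1`, `q2`,
#'   `q3`, `max`.
#' @export
delta_e_summary <- function(a, b) {
  a <- as_rgb_image(a); b <- as_rgb_image(b)
  if (!identical(dim(a), dim(b))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
  de <- delta_e_map(a, b)
  q <- stats::quantile(de, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(
    list(mean = mean(de), q1 = q[1], q2 = q[2], q3 = q[3], max = max(de)),
    class = "delta_e_summary"
  )
}

# Per-pixel CIE76 distances as a vector.
delta_e_map <- function(a, b) {
  la <- matrix(srgb_matrix_to_lab(matrix(as.numeric(a), ncol = 3L)), ncol = 3L)
  lb <- matrix(srgb_matrix_to_lab(matrix(as.numeric(b), ncol = 3L)), ncol = 3L)
  sqrt(rowSums((la - lb)^2))
}

#' @export
print.delta_e_summary <- function(x, ...) {
  cat(sprintf("dE  mean %.3f | Q1 %.3f  Q2 %.3f  Q3 %.3f | max %.3f\n",
              x$mean, x$q1, x$q2, x$q3, x$max))
  invisible(x)
}

#' Classify cast severity from a mean chromatic distance
#'
#' Applies the working criteria used throughout the package: a mean CIE76
#' distance below 6 is visually the same image, below 15 a mild cast, and 15
#' or above a cast (the boundary value is assigned to the more severe class,
#' erring towards flagging).
#'
#' @param mean_delta_e Non-negative mean CIE76 distance.
#' @return One of `"same"`, `"mild_cast"`, `"cast"`.
#' @export
classify_cast <- function(mean_delta_e) {
  if (!is.numeric(mean_delta_e) || length(mean_delta_e) != 1L ||
      is.na(mean_delta_e) || mean_delta_e < 0) {
    stop("mean_delta_e must be a single non-negative number", call. = FALSE)
  }
  if (mean_delta_e < 6) "same" else if (mean_delta_e < 15) "mild_cast" else "cast"
}

#' Image quality metrics
#'
#' `mae()` and `rmse()` are mean absolute and root-mean-square pixel error on
#' levels normalized to `[0, 1]`. `psnr()` is the peak signal-to-noise ratio
#' in decibels with a peak level of 255 (`Inf` for identical images).
#' `ssim()` is the structural similarity index: per channel, means, variances
#' and covariance are estimated under an 11x11 Gaussian window (sigma 1.5) on
#' 0-255 levels with stabilizers `c1 = (0.01*255)^2`, `c2 = (0.03*255)^2`,
#' and the channel means of the resulting maps are averaged.
#'
#' @param reference,test [rgb_image]s of identical dimensions.
#' @return A single number.
#' @export
mae <- function(reference, test) {
  check_pair(reference, test)
  mean(abs(as.numeric(reference) - as.numeric(test))) / 255
}

#' @rdname mae
#' @export
rmse <- function(reference, test) {
  check_pair(reference, test)
  sqrt(mean((as.numeric(reference) - as.numeric(test))^2)) / 255
}

#' @rdname mae
#' @export
psnr <- function(reference, test) {
  r <- rmse(reference, test)
  if (r == 0) Inf else 20 * log10(1 / r)  # == 20*log10(255 / (255*r))
}

#' @rdname mae
#' @export
ssim <- function(reference, test) {
  check_pair(reference, test)
  d <- dim(reference)
  if (min(d[1:2]) < 11L) {
    stop("ssim requires images of at least 11x11 pixels", call. = FALSE)
  }
  w <- ssim_window()
  c1 <- (0.01 * 255)^2
  c2 <- (0.03 * 255)^2
  vals <- vapply(1:3, function(ch) {
    x <- matrix(as.numeric(reference[, , ch]), d[1], d[2])
    y <- matrix(as.numeric(test[, , ch]), d[1], d[2])
    mx <- conv2_valid(x, w)
    my <- conv2_valid(y, w)
    sxx <- conv2_valid(x * x, w) - mx * mx
    syy <- conv2_valid(y * y, w) - my * my
    sxy <- conv2_valid(x * y, w) - mx * my
    map <- ((2 * mx * my + c1) * (2 * sxy + c2)) /
      ((mx * mx + my * my + c1) * (sxx + syy + c2))
    mean(map)
  }, numeric(1))
  mean(vals)
}

ssim_window <- function() {
  g <- exp(-((-5:5)^2) / (2 * 1.5^2))
  w <- outer(g, g)
  w / sum(w)
}

check_pair <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
  invisible(NULL)
}

#' Full quality report for one image pair
#'
#' Bundles every evaluation metric for a (reference, test) pair: PSNR (dB,
#' 0-255 scale, `Inf` for identical images), SSIM, MAE and RMSE on levels
#' normalized to `[0, 1]`, the five-level CIE76 distance summary, and the
#' cast class implied by the mean distance.
#'
#' @param reference,test [rgb_image]s of identical dimensions.
#' @return A list of class `quality_report` with fields `psnr`, `ssim`,
#'   `mae`, `rmse`, `delta_e` (a [delta_e_summary]) and `cast`.
#' @export
quality_report <- function(reference, test) {
  reference <- as_rgb_image(reference); test <- as_rgb_image(test)
  check_pair(reference, test)
  de <- delta_e_summary(reference, test)
  m <- mae(reference, test)
  r <- rmse(reference, test)
  structure(
    list(
      psnr = if (r == 0) Inf else 20 * log10(1 / r),
      ssim = ssim(reference, test),
      mae = m,
      rmse = r,
      delta_e = de,
      cast = classify_cast(de$mean)
    ),
    class = "quality_report"
  )
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("PSNR %.4f dB | SSIM %.4f | MAE %.4f | RMSE %.4f [0-1 scale]\n",
              x$psnr, x$ssim, x$mae, x$rmse))
  print(x$delta_e)
  cat("cast class:", x$cast, "\n")
  invisible(x)
}

# One flat row per report, in the conventional column order.
report_row <- function(x) {
  data.frame(
    PSNR = x$psnr, SSIM = x$ssim,
    E_mean = x$delta_e$mean, E_Q1 = x$delta_e$q1, E_Q2 = x$delta_e$q2,
    E_Q3 = x$delta_e$q3, E_Max = x$delta_e$max,
    MAE = x$mae, RMSE = x$rmse
  )
}

#' Write a table of quality reports to CSV
#'
#' Columns follow the conventional order PSNR, SSIM, E_mean, E_Q1, E_Q2,
#' E_Q3, E_Max, MAE, RMSE (MAE/RMSE on the normalized 0-1 scale, PSNR on the
#' 0-255 scale).
#'
#' @param reports A data frame as returned by [evaluate_corrector()], or a
#'   list of [quality_report] objects.
#' @param path Output CSV path.
#' @export
write_quality_csv <- function(reports, path) {
  if (!is.data.frame(reports)) {
    reports <- do.call(rbind, lapply(reports, report_row))
  }
  utils::write.csv(reports, path, row.names = FALSE)
  invisible(path)
}
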
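#' Evaluate a corrector on the test pairs of a dataset
#'
#' Applies `correct_fn` to every biased test patch and scores the result
#' against the clean patch with [quality_report()]. An `"original"` row
#' (biased scored directly against clean, i.e. the uncorrected baseline) is
#' emitted alongside every `"corrected"` row so improvement can be read off
#' per pair and per bias kind.
#'
#' @param correct_fn Function mapping an [rgb_image] to a corrected
#'   [rgb_image] (e.g. `gray_world`, or `function(im) correct_image(model, im)`).
#' @param data A `patch_dataset`.
#' @param split Which split to evaluate (default `"test"`).
#' @return A data frame with columns `pair`, `source`, `kind`, `state` and
#'   the metric columns PSNR, SSIM, E_mean, E_Q1, E_Q2, E_Q3, E_Max, MAE,
#'   RMSE.
#' @export
evaluate_corrector <- function(correct_fn, data, split = "test") {
  stopifnot(inherits(data, "patch_dataset"))
  idx <- which(data$info$split == split)
  if (!length(idx)) stop("no pairs in split '", split, "'", call. = FALSE)
  rows <- vector("list", 2L * length(idx))
  kind <- if (is.null(data$info$kind)) rep(NA_character_, nrow(data$info)) else data$info$kind
  for (j in seq_along(idx)) {
    i <- idx[j]
    pr <- dataset_pair(data, i)
    meta <- data.frame(pair = i, source = data$info$source[i], kind = kind[i])
    rows[[2L * j - 1L]] <- cbind(meta, state = "original",
                                 report_row(quality_report(pr$clean, pr$biased)))
    rows[[2L * j]] <- cbind(meta, state = "corrected",
                            report_row(quality_report(pr$clean, correct_fn(pr$biased))))
  }
  do.call(rbind, rows)
}

#' Bootstrap summary of a per-image metric
#'
#' Draws `n_boot` resamples with replacement at the size of the metric list,
#' takes the mean of each resample, and reports the mean and standard
#' deviation of those resample means — the form in which model performance
#' is quoted and compared.
#'
#' @param values Numeric vector of per-image (or per-patch) metric values.
#' @param n_boot Number of bootstrap resamples (default 40).
#' @param seed Integer seed.
#' @return A list of class `bootstrap_report` with `n_boot`, `mean`, `sd`
#'   and the individual `resample_means`.
#' @export
bootstrap_evaluate <- function(values, n_boot = 40L, seed = 1) {
  if (!is.numeric(values) || !length(values)) {
    stop("values must be a non-empty numeric vector", call. = FALSE)
  }
  n <- length(values)
  means <- with_seed(seed, {
    vapply(seq_len(n_boot),
           function(i) mean(values[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  structure(
    list(n_boot = as.integer(n_boot), mean = mean(means),
         sd = stats::sd(means), resample_means = means),
    class = "bootstrap_report"
  )
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat(sprintf("bootstrap (%d resamples): %.4f +/- %.4f\n", x$n_boot, x$mean, x$sd))
  invisible(x)
}

#' Paired t-test between two methods' per-image metrics
#'
#' Classical paired t statistic on the differences with a two-sided p-value
#' from the t distribution on `n - 1` degrees of freedom. Identical vectors
#' (all differences zero) are reported as `t = 0`, `p = 1`. Significance is
#' declared at `p < alpha` (default 0.001). No multiple-testing correction
#' is applied when the test is repeated across bias scenarios and metrics;
#' reported p-values are raw.
#'
#' @param a,b Numeric vectors of equal length (at least 2), paired by image.
#' @param alpha Significance level (default 0.001).
#' @return A list of class `t_test_result` with `t_statistic`, `p_value`,
#'   `df` and `significant`.
#' @export
paired_t_test <- function(a, b, alpha = 0.001) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != length(b)) {
    stop("a and b must be numeric vectors of equal length", call. = FALSE)
  }
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      t <- 0; p <- 1
    } else {
      t <- sign(mean(d)) * Inf; p <- 0
    }
    res <- list(t_statistic = t, p_value = p, df = n - 1L)
  } else {
    tt <- stats::t.test(a, b, paired = TRUE)
    res <- list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
                df = unname(tt$parameter))
  }
  res$significant <- res$p_value < alpha
  structure(res, class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("paired t = %.4f, df = %d, p = %.3g%s\n", x$t_statistic, x$df,
              x$p_value, if (x$significant) " (significant)" else ""))
  invisible(x)
}
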
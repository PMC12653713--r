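#' Extract sliding-window patches from an image
#'
#' Square crops of side `size` at offsets `0, step, 2*step, ...` along both
#' axes, kept while the window fits inside the image, in row-major order.
#' A 640x640 image at size 160 / step 80 yields 7 x 7 = 49 patches.
#'
#' @param img An [rgb_image].
#' @param size Patch side in pixels.
#' @param step Offset between consecutive windows.
#' @return A list of [rgb_image] patches.
#' @export
extract_patches <- function(img, size = 160L, step = 80L) {
  img <- as_rgb_image(img)
  d <- dim(img)
  if (size > min(d[1:2])) {
    stop("patch size exceeds image dimensions", call. = FALSE)
  }
  if (step < 1L) stop("step must be at least 1", call. = FALSE)
  offs_r <- seq.int(1L, d[1] - size + 1L, by = step)
  offs_c <- seq.int(1L, d[2] - size + 1L, by = step)
  out <- vector("list", length(offs_r) * length(offs_c))
  i <- 0L
  for (r in offs_r) {
    for (cc in offs_c) {
      i <- i + 1L
      p <- unclass(img)[r:(r + size - 1L), cc:(cc + size - 1L), , drop = FALSE]
      out[[i]] <- structure(p, class = c("rgb_image", "array"))
    }
  }
  out
}

#' Assign train/val/test splits by source image
#'
#' Splitting is done at the source-image level, never at the patch level:
#' patches cut from one photograph are near-duplicates of their neighbours,
#' and letting them straddle splits would leak training content into the
#' test set. Source images are shuffled with the given seed and allocated to
#' splits in the requested proportions (each split gets at least one image).
#'
#' @param pairs_info Data frame with one row per patch pair and a `source`
#'   column identifying the originating image.
#' @param ratios Train/val/test proportions summing to 1 (default 60/30/10).
#' @param seed Integer seed for the shuffle.
#' @return `pairs_info` with an added `split` factor column.
#' @export
split_dataset <- function(pairs_info, ratios = c(0.6, 0.3, 0.1), seed = 1) {
  if (!is.data.frame(pairs_info) || is.null(pairs_info$source)) {
    stop("pairs_info must be a data frame with a 'source' column", call. = FALSE)
  }
  if (length(ratios) != 3L || any(ratios <= 0) ||
      abs(sum(ratios) - 1) > 1e-8) {
    stop("ratios must be three positive numbers summing to 1", call. = FALSE)
  }
  sources <- unique(pairs_info$source)
  n <- length(sources)
  if (n < 3L) {
    stop("need at least 3 source images to populate all three splits", call. = FALSE)
  }
  counts <- diff(c(0, round(cumsum(ratios) * n)))
  while (any(counts == 0L)) {
    counts[which.max(counts)] <- counts[which.max(counts)] - 1L
    counts[which.min(counts)] <- counts[which.min(counts)] + 1L
  }
  perm <- with_seed(seed, sample(sources))
  lab <- rep(c("train", "val", "test"), counts)
  assign <- stats::setNames(lab, perm)
  pairs_info$split <- factor(assign[as.character(pairs_info$source)],
                             levels = c("train", "val", "test"))
  pairs_info
}

#' Paired-patch dataset container
#'
#' Holds aligned (biased, clean) 8-bit patches as `(H, W, 3, P)` integer
#' arrays together with per-pair metadata (source image, bias kind, split)
#' and the manifest of cast specifications that produced the biased side.
#'
#' @param biased,clean `(H, W, 3, P)` arrays of 8-bit levels.
#' @param info Data frame with one row per pair (columns `source`, `split`,
#'   optionally `kind`).
#' @param manifest Optional data frame of the [bias_spec()] parameters used
#'   per source image and kind.
#' @return A list of class `patch_dataset`.
#' @export
patch_dataset <- function(biased, clean, info, manifest = NULL) {
  if (!identical(dim(biased), dim(clean))) {
    stop("biased and clean arrays must have identical dimensions", call. = FALSE)
  }
  d <- dim(biased)
  if (length(d) != 4L || d[3] != 3L) {
    stop("patch arrays must be (H, W, 3, P)", call. = FALSE)
  }
  if (nrow(info) != d[4]) {
    stop("info must have one row per patch pair", call. = FALSE)
  }
  if (is.null(info$split)) {
    stop("info must carry a 'split' column (see split_dataset)", call. = FALSE)
  }
  structure(list(biased = biased, clean = clean, info = info,
                 manifest = manifest),
            class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  d <- dim(x$biased)
  tab <- table(x$info$split)
  cat(sprintf("<patch_dataset: %d pairs of %dx%d patches | train %d / val %d / test %d>\n",
              d[4], d[1], d[2], tab[["train"]], tab[["val"]], tab[["test"]]))
  invisible(x)
}

# Pull one pair out of a dataset as rgb_images.
dataset_pair <- function(data, i) {
  b <- data$biased[, , , i, drop = TRUE]
  c_ <- data$clean[, , , i, drop = TRUE]
  storage.mode(b) <- "double"
  storage.mode(c_) <- "double"
  list(biased = structure(b, class = c("rgb_image", "array")),
       clean = structure(c_, class = c("rgb_image", "array")))
}
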
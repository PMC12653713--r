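#' Training hyperparameters
#'
#' Defaults follow the study conditions used for the full-scale network:
#' batch size 32, 200 epochs, Adam with initial learning rate 1e-4 and L2
#' weight decay 1e-5, and a plateau scheduler that halves the learning rate
#' when the validation loss has not improved by at least `plateau_tol` for
#' `scheduler_patience` consecutive epochs.
#'
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param learning_rate Initial Adam learning rate.
#' @param weight_decay L2 penalty on convolution weights.
#' @param scheduler_factor Multiplicative learning-rate reduction factor.
#' @param scheduler_patience Epochs without improvement before reduction.
#' @param plateau_tol Minimum validation-loss improvement that counts.
#' @param seed Integer seed controlling shuffling (and nothing else).
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, epochs = 200L, learning_rate = 1e-4,
                         weight_decay = 1e-5, scheduler_factor = 0.5,
                         scheduler_patience = 15L, plateau_tol = 1e-6,
                         seed = 1L) {
  cfg <- list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
              learning_rate = learning_rate, weight_decay = weight_decay,
              scheduler_factor = scheduler_factor,
              scheduler_patience = as.integer(scheduler_patience),
              plateau_tol = plateau_tol, seed = as.integer(seed))
  if (cfg$batch_size < 1L || cfg$epochs < 1L || cfg$learning_rate <= 0 ||
      cfg$weight_decay < 0 || cfg$scheduler_factor <= 0 ||
      cfg$scheduler_factor >= 1 || cfg$scheduler_patience < 1L) {
    stop("invalid train_config", call. = FALSE)
  }
  if (cfg$scheduler_patience >= cfg$epochs) {
    stop("scheduler_patience must be smaller than epochs", call. = FALSE)
  }
  structure(cfg, class = "train_config")
}

#' Mean squared error loss
#'
#' Mean of squared elementwise differences over all positions; the training
#' objective of both networks.
#'
#' @param predicted,target Arrays of identical shape.
#' @return A single number.
#' @export
mse_loss <- function(predicted, target) {
  if (!identical(dim(predicted), dim(target))) {
    stop("predicted and target must have identical shapes", call. = FALSE)
  }
  mean((predicted - target)^2)
}

adam_init <- function(params) {
  st <- list(t = 0L, m = list(), v = list())
  for (nm in names(params)) {
    p <- params[[nm]]
    fields <- intersect(names(p), c("W", "b", "gamma", "beta"))
    st$m[[nm]] <- lapply(p[fields], function(v) v * 0)
    st$v[[nm]] <- lapply(p[fields], function(v) v * 0)
  }
  st
}

adam_step <- function(params, grads, st, lr, wd, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - b1^st$t
  bc2 <- 1 - b2^st$t
  for (nm in names(grads)) {
    for (f in names(grads[[nm]])) {
      g <- grads[[nm]][[f]]
      if (f == "W" && wd > 0) g <- g + wd * params[[nm]][[f]]
      st$m[[nm]][[f]] <- b1 * st$m[[nm]][[f]] + (1 - b1) * g
      st$v[[nm]][[f]] <- b2 * st$v[[nm]][[f]] + (1 - b2) * g * g
      params[[nm]][[f]] <- params[[nm]][[f]] -
        lr * (st$m[[nm]][[f]] / bc1) / (sqrt(st$v[[nm]][[f]] / bc2) + eps)
    }
  }
  list(params = params, state = st)
}

#' Train a correction network on a patch dataset
#'
#' Adam optimization of the mean-squared-error objective with the given
#' hyperparameters. The validation loss drives a reduce-on-plateau learning
#' rate schedule and best-checkpoint selection (lowest validation loss, with
#' BN running statistics as of that epoch). The per-epoch history records
#' losses, PSNR (derived from the epoch MSE, identical on the 0-1 and 0-255
#' conventions) and the learning rate.
#'
#' @param model A `cc_model` from [build_tococonet()] or [build_dccn()].
#' @param data A `patch_dataset` with non-empty train and val splits.
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch?
#' @return A list with `model` (best-validation checkpoint) and `history`
#'   (a data frame of class `train_history`).
#' @export
train_model <- function(model, data, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "cc_model"), inherits(data, "patch_dataset"),
            inherits(cfg, "train_config"))
  tr <- which(data$info$split == "train")
  va <- which(data$info$split == "val")
  if (!length(tr) || !length(va)) {
    stop("dataset must have non-empty train and val splits", call. = FALSE)
  }
  adam <- adam_init(model$params)
  lr <- cfg$learning_rate
  best_val <- Inf
  best <- list(params = model$params, bn_state = model$bn_state)
  stall <- 0L
  hist <- vector("list", cfg$epochs)

  run_eval <- function(idx) {
    tot <- 0
    for (bi in batch_indices(length(idx), cfg$batch_size)) {
      ids <- idx[bi]
      x <- dataset_tensor(data, ids, "biased")
      y <- dataset_tensor(data, ids, "clean")
      pred <- model_forward(model, x, training = FALSE)$y
      tot <- tot + mse_loss(pred, y) * length(ids)
    }
    tot / length(idx)
  }

  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(tr)
      ep_loss <- 0
      for (bi in batch_indices(length(ord), cfg$batch_size)) {
        ids <- ord[bi]
        x <- dataset_tensor(data, ids, "biased")
        y <- dataset_tensor(data, ids, "clean")
        fw <- model_forward(model, x, training = TRUE)
        model$bn_state <- fw$bn_state
        loss <- mse_loss(fw$y, y)
        if (!is.finite(loss)) {
          stop("non-finite training loss at epoch ", ep,
               "; lower the learning rate", call. = FALSE)
        }
        ep_loss <- ep_loss + loss * length(ids)
        gy <- 2 * (fw$y - y) / length(y)
        grads <- model_backward(model, fw$caches, gy)
        upd <- adam_step(model$params, grads, adam, lr, cfg$weight_decay)
        model$params <- upd$params
        adam <- upd$state
      }
      train_loss <- ep_loss / length(ord)
      val_loss <- run_eval(va)
      if (val_loss < best_val - cfg$plateau_tol) {
        best_val <- val_loss
        best <- list(params = model$params, bn_state = model$bn_state)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$scheduler_patience) {
          lr <- lr * cfg$scheduler_factor
          stall <- 0L
        }
      }
      hist[[ep]] <- data.frame(
        epoch = ep, train_loss = train_loss, val_loss = val_loss,
        train_psnr = 10 * log10(1 / train_loss),
        val_psnr = 10 * log10(1 / val_loss), lr = lr
      )
      if (verbose) {
        message(sprintf("epoch %3d  train %.3e  val %.3e  lr %.2e",
                        ep, train_loss, val_loss, lr))
      }
    }
  })
  model$params <- best$params
  model$bn_state <- best$bn_state
  history <- do.call(rbind, hist)
  class(history) <- c("train_history", "data.frame")
  list(model = model, history = history)
}

batch_indices <- function(n, size) {
  split(seq_len(n), ceiling(seq_len(n) / size))
}

# (H, W, 3, length(ids)) float tensor in [0, 1] from stored 8-bit patches.
dataset_tensor <- function(data, ids, which) {
  x <- data[[which]][, , , ids, drop = FALSE]
  storage.mode(x) <- "double"
  x / 255
}

#' Write a training history to CSV
#'
#' @param history A `train_history` data frame.
#' @param path Output CSV path (columns epoch, train_loss, val_loss,
#'   train_psnr, val_psnr, lr).
#' @export
write_history_csv <- function(history, path) {
  utils::write.csv(as.data.frame(history), path, row.names = FALSE)
  invisible(path)
}
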